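test_that("zero-noise, zero-lapse policies reproduce metrics exactly", {
  cfg <- task_config(n_trials = 5)
  p <- controller_params(timing_sd = 0, lapse_prob = 0)
  m1 <- session_metrics(run_session(cfg, make_policy(p), seed = 1))
  m2 <- session_metrics(run_session(cfg, make_policy(p), seed = 999))
  expect_identical(m1, m2)
  expect_identical(length(unique(m1$tint_ms)), 1L)
})

test_that("a pure-lapse policy never moves: zero TinT, undefined RT", {
  cfg <- task_config(n_trials = 10)
  p <- controller_params(lapse_prob = 1)
  m <- session_metrics(run_session(cfg, make_policy(p), seed = 3))
  expect_true(all(m$tint_ms == 0))
  expect_true(all(is.na(m$rt_ms)))
  expect_true(all(is.na(m$sr)))
  summ <- summarize_session(m)
  expect_true(is.na(summ$mean_rt))
  expect_identical(summ$n_rt, 0L)
})

test_that("expected time in target decreases with timing noise", {
  cfg <- task_config(n_trials = 200)
  sds <- c(0, 0.05, 0.15, 0.3)
  set.seed(11)
  stats_by_sd <- lapply(sds, function(s) {
    m <- session_metrics(run_session(
      cfg, make_policy(controller_params(timing_sd = s, lapse_prob = 0))
    ))
    c(mean = mean(m$tint_ms), se = sd(m$tint_ms) / sqrt(nrow(m)))
  })
  means <- vapply(stats_by_sd, `[[`, numeric(1), "mean")
  ses <- vapply(stats_by_sd, `[[`, numeric(1), "se")
  for (k in seq_len(length(sds) - 1)) {
    tol <- 2 * sqrt(ses[k]^2 + ses[k + 1]^2)
    expect_lte(means[k + 1], means[k] + tol)
  }
})

test_that("covariate links map onto gameplay in the declared directions", {
  # all-zero coefficients and SDs: everyone gets the intercepts
  flat <- covariate_link(
    t_go_mean = link_term(1.7), tau_right = link_term(0.7),
    rho = link_term(1), t_rev_gap = link_term(0),
    timing_sd = link_term(0.05), lapse_prob = link_term(0.02)
  )
  co <- generate_cohort(cohort_config(n = 20), seed = 2)
  p <- link_params(co, flat)
  expect_true(all(p$t_go_mean == 1.7))
  expect_true(all(p$timing_sd == 0.05))
  expect_identical(p$t_rev_mean, p$t_go_mean + p$tau_right)

  # a positive age coefficient raises older participants' timing noise
  age_link <- covariate_link(
    timing_sd = link_term(0.05, c(age_z = 0.01), sd = 0,
                          lower = 0.001, upper = 0.3)
  )
  co2 <- generate_cohort(cohort_config(n = 1000), seed = 4)
  p2 <- link_params(co2, age_link)
  older <- co2$age > median(co2$age)
  expect_gt(mean(p2$timing_sd[older]), mean(p2$timing_sd[!older]))

  # a negative carrier effect on planned exit lowers carriers' realized RT
  rt_link <- covariate_link(
    t_go_mean = link_term(1.7, c(carrier = -0.1), sd = 0,
                          lower = 1.3, upper = 3.5)
  )
  co3 <- generate_cohort(cohort_config(n = 300), seed = 5)
  tab <- simulate_study(co3, link = rt_link, seed = 6)
  carrier <- carrier_status(co3$apoe_genotype)
  expect_lt(mean(tab$mean_rt[carrier]), mean(tab$mean_rt[!carrier]))
})

test_that("default link clamps fewer than 1% of participants per parameter", {
  co <- generate_cohort(cohort_config(n = 2000), seed = 8)
  expect_no_warning(p <- link_params(co, covariate_link()))
  clamping <- attr(p, "clamping")
  expect_true(all(clamping$n_clamped <= 0.01 * nrow(co)))
})

test_that("a link naming an absent covariate is a configuration error", {
  co <- generate_cohort(cohort_config(n = 10), seed = 1)
  co$skill_z <- NULL
  expect_error(link_params(co, covariate_link()), "skill_z")
})

test_that("controller parameter validation rejects invalid values", {
  expect_error(controller_params(lapse_prob = 1.5), "lapse_prob")
  expect_error(controller_params(timing_sd = -0.1), "non-negative")
  expect_error(controller_params(t_go_mean = Inf), "finite")
})
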