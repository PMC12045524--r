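test_that("model specifications mirror the study's five equations", {
  m1 <- model_spec(1)
  expect_identical(m1$outcome, "carrier")
  expect_identical(m1$family, "binomial")
  expect_identical(m1$performance, "rt")
  expect_setequal(m1$controls,
                  c("age_z", "male", "hour_cos_z", "education", "svrt_z", "pal_z"))

  m2 <- model_spec(2)
  expect_identical(m2$outcome, "male")
  expect_true("carrier" %in% m2$controls)

  m3 <- model_spec("age_linear")
  expect_identical(m3$outcome, "age")
  expect_identical(m3$family, "gaussian")

  m4 <- model_spec(4)
  expect_true(m4$interaction)
  expect_true("tint_z:male" %in% m4$predictors)
  m5 <- model_spec(5)
  expect_identical(m5$outcome, "pal_adjusted")

  expect_error(model_spec(6), "1-5")
  expect_error(model_spec(1, performance = "speed"), "tint, rt, sr, tr")
})

test_that("logistic fit recovers a known coefficient and reports OR = exp(beta)", {
  set.seed(91)
  n <- 2000
  # carrier status generated from rt_z with beta = -1; all else noise
  d <- tibble::tibble(
    rt_z = rnorm(n), age_z = rnorm(n), male = runif(n) < 0.3,
    hour_cos_z = rnorm(n), svrt_z = rnorm(n), pal_z = rnorm(n),
    education = factor(sample(education_levels(), n, replace = TRUE),
                       levels = education_levels())
  )
  d$carrier <- runif(n) < plogis(-1 * d$rt_z)
  fit <- fit_model(model_spec(1), d, ci_method = "wald")
  co <- tidy(fit)
  est <- co$estimate[co$term == "rt_z"]
  se <- co$std.error[co$term == "rt_z"]
  expect_lt(abs(est - (-1)), 3 * se)
  expect_equal(co$odds.ratio, exp(co$estimate), tolerance = 1e-12)
  expect_true(all(co$conf.low <= co$conf.high))
})

test_that("profile CIs bracket the estimate and logistic outcomes are checked", {
  tab <- simulate_study(generate_cohort(cohort_config(n = 80), seed = 92), seed = 93)
  std <- standardize_analysis(tab)
  fit <- fit_model(model_spec(1), std, ci_method = "profile")
  co <- tidy(fit)
  expect_true(all(co$conf.low < co$estimate & co$estimate < co$conf.high))
  g <- glance(fit)
  expect_identical(g$model_id, 1L)
  expect_identical(g$n_obs, 80L)
  expect_identical(g$family, "binomial")
  ex <- tidy(fit, exponentiate = TRUE)
  expect_identical(names(ex)[2], "odds.ratio")

  bad <- dplyr::mutate(std, carrier = as.numeric(carrier))
  expect_error(fit_model(model_spec(1), bad), "must be logical")
})

test_that("linearly rescaling a predictor rescales its coefficient", {
  tab <- simulate_study(generate_cohort(cohort_config(n = 150), seed = 94), seed = 95)
  std <- standardize_analysis(tab)
  f1 <- fit_model(model_spec(2), std, ci_method = "none")
  std2 <- dplyr::mutate(std, tint_z = tint_z * 2)
  f2 <- fit_model(model_spec(2), std2, ci_method = "none")
  b1 <- f1$coefs$estimate[f1$coefs$term == "tint_z"]
  b2 <- f2$coefs$estimate[f2$coefs$term == "tint_z"]
  expect_equal(b1, 2 * b2, tolerance = 1e-6)
})

test_that("the sex-by-TinT interaction is detected with high power at n = 500", {
  hits <- vapply(1:30, function(r) {
    set.seed(9000 + r)
    co <- generate_cohort(cohort_config(n = 500))
    std <- standardize_analysis(simulate_study(co))
    co4 <- tidy(fit_model(model_spec(4), std, ci_method = "none"))
    est <- co4$estimate[co4$term == "tint_z:maleTRUE"]
    p <- co4$p.value[co4$term == "tint_z:maleTRUE"]
    est > 0 && p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("model 5 on delay-adjusted PAL tracks model 4", {
  tab <- simulate_study(generate_cohort(cohort_config(n = 200), seed = 96), seed = 97)
  std <- standardize_analysis(tab)
  f4 <- fit_model(model_spec(4), std, ci_method = "none")
  f5 <- fit_model(model_spec(5), std, ci_method = "none")
  b4 <- f4$coefs$estimate[f4$coefs$term == "tint_z:maleTRUE"]
  b5 <- f5$coefs$estimate[f5$coefs$term == "tint_z:maleTRUE"]
  # the adjustment shifts PAL by a near-constant offset, so the interaction
  # is nearly unchanged
  expect_lt(abs(b4 - b5), 1)
  expect_identical(f5$spec$outcome, "pal_adjusted")
})
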