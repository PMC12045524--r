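test_that("carrier status partitions the six observed genotypes", {
  expect_identical(carrier_status(c("2/2", "2/3", "3/3")), rep(FALSE, 3))
  expect_identical(carrier_status(c("2/4", "3/4", "4/4")), rep(TRUE, 3))
  expect_error(carrier_status("4/5"), "malformed")
  expect_error(carrier_status("33"), "malformed")
  expect_error(carrier_status(NA_character_), "malformed")
})

test_that("cosine hour closes the midnight gap", {
  expect_identical(cosine_hour(0), 1)
  expect_equal(cosine_hour(12), -1)
  expect_equal(cosine_hour(23), cos(pi / 12))
  expect_equal(cosine_hour(23), cosine_hour(1))
  for (h in 1:23) expect_equal(cosine_hour(h), cosine_hour(24 - h))
  expect_error(cosine_hour(24), "\\[0, 24\\)")
  expect_error(cosine_hour(-1), "\\[0, 24\\)")
})

test_that("PAL delay adjustment is 0.2 points per year", {
  expect_identical(as.numeric(adjust_pal(20, 0)), 20)
  expect_equal(as.numeric(adjust_pal(20, 5)), 19)
  expect_equal(as.numeric(adjust_pal(20, 5.9)), 18.82)
  # linear in the delay
  yrs <- seq(0, 10, by = 0.5)
  expect_equal(as.numeric(adjust_pal(30, yrs)), 30 - 0.2 * yrs)
  expect_error(adjust_pal(20, -1), ">= 0")
})

test_that("standardization gives exact z-scores and inverts cleanly", {
  expect_equal(z_score(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50)
  expect_equal(z_score(z_score(x)), z_score(x), tolerance = 1e-12)
  expect_error(z_score(rep(1, 5)), "zero-variance")

  tab <- simulate_study(generate_cohort(cohort_config(n = 60), seed = 41), seed = 42)
  std <- standardize_analysis(tab)
  tr <- attr(std, "transforms")
  expect_true(all(c("age_z", "svrt_z", "pal_z", "pal_adj_z", "hour_cos_z",
                    "tint_z", "rt_z", "sr_z", "tr_z") %in% names(std)))
  for (z in tr$z_name) {
    expect_lt(abs(mean(std[[z]])), 1e-9)
    expect_lt(abs(sd(std[[z]]) - 1), 1e-9)
  }
  expect_identical(std$male, tab$sex == "male")
  expect_identical(std$carrier, carrier_status(tab$apoe_genotype))
  expect_identical(levels(std$education)[1], "high school diploma")

  back <- unstandardize(std)
  for (v in tr$variable) expect_equal(back[[v]], as.numeric(std[[v]]),
                                      tolerance = 1e-9)

  degenerate <- dplyr::mutate(tab, age = 50)
  expect_error(standardize_analysis(degenerate), "age")
})

test_that("reference percentiles follow the midrank convention", {
  ref <- tibble::tibble(
    age = rep(65, 11), sex = "female",
    education = "four-year degree",
    pal_raw = c(5, 8, 11, 14, 17, 20, 23, 26, 29, 32, 35)
  )
  me <- tibble::tibble(age = 67, sex = "female", education = "four-year degree")
  expect_equal(percentile_vs_reference(20, me, ref, "pal_raw"), 50)
  expect_equal(percentile_vs_reference(36, me, ref, "pal_raw"), 100)
  expect_equal(percentile_vs_reference(0, me, ref, "pal_raw"), 0)

  # brute-force rank oracle on a random reference
  set.seed(51)
  ref2 <- tibble::tibble(
    age = runif(200, 60, 70), sex = "female",
    education = "four-year degree", score = rnorm(200)
  )
  for (v in c(-1, 0, 0.5)) {
    got <- percentile_vs_reference(v, me, ref2, "score")
    expect_equal(got, 100 * mean(ref2$score < v))
  }

  # empty stratum falls back to sex x education with a warning
  older <- tibble::tibble(age = 95, sex = "female", education = "four-year degree")
  expect_warning(p <- percentile_vs_reference(20, older, ref, "pal_raw"),
                 "empty age-decade stratum")
  expect_equal(p, 50)
  expect_error(
    suppressWarnings(percentile_vs_reference(
      20, tibble::tibble(age = 67, sex = "male", education = "some college"),
      ref, "pal_raw"
    )),
    "no matching reference stratum"
  )
})
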