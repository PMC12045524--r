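test_that("VIFs are exactly 1 for orthogonal predictors and none are removed", {
  set.seed(71)
  m <- scale(matrix(rnorm(300), 100, 3), center = TRUE, scale = FALSE)
  q <- qr.Q(qr(m))  # orthonormal and column-centered, so cor(q) = I
  d <- tibble::tibble(a = q[, 1], b = q[, 2], c = q[, 3])
  res <- vif_filter(d, c("a", "b", "c"))
  expect_identical(res$removed, character())
  expect_equal(res$vif$gvif, rep(1, 3), tolerance = 1e-8)
})

test_that("a duplicated predictor has infinite VIF and loses exactly one copy", {
  set.seed(72)
  d <- tibble::tibble(a = rnorm(60), c = rnorm(60))
  d$b <- d$a
  res <- vif_filter(d, c("a", "b", "c"))
  expect_identical(length(res$removed), 1L)
  expect_true(res$removed %in% c("a", "b"))
  expect_identical(sort(c(res$removed, res$retained)), c("a", "b", "c"))
})

test_that("VIFs match the 1/(1 - R^2) closed form and car's GVIF", {
  set.seed(73)
  n <- 300
  z <- rnorm(n)
  d <- tibble::tibble(
    x1 = z + rnorm(n, sd = 0.45),
    x2 = z + rnorm(n, sd = 0.45),
    x3 = z + rnorm(n, sd = 0.45)
  )
  res <- supergee:::term_vifs(d, c("x1", "x2", "x3"))
  for (j in 1:3) {
    r2 <- summary(lm(reformulate(paste0("x", setdiff(1:3, j)), paste0("x", j)),
                     data = d))$r.squared
    expect_equal(res$gvif[j], 1 / (1 - r2), tolerance = 1e-8)
  }

  # factor terms: generalized VIF equals car's, coding-invariantly
  d$f <- factor(sample(letters[1:3], n, replace = TRUE))
  d$y <- rnorm(n)
  ours <- supergee:::term_vifs(d, c("x1", "x2", "f"))
  theirs <- car::vif(lm(y ~ x1 + x2 + f, data = d))
  expect_equal(ours$gvif, unname(theirs[, "GVIF"]), tolerance = 1e-8)
  expect_equal(ours$gvif_adj, unname(theirs[, "GVIF^(1/(2*Df))"]),
               tolerance = 1e-8)
})

test_that("VIF filtering does not depend on predictor order", {
  set.seed(74)
  n <- 200
  z <- rnorm(n)
  d <- tibble::tibble(
    a = z + rnorm(n, sd = 0.2),
    b = z + rnorm(n, sd = 0.2),
    c = rnorm(n),
    e = z + rnorm(n, sd = 0.25)
  )
  r1 <- vif_filter(d, c("a", "b", "c", "e"))
  r2 <- vif_filter(d, c("e", "c", "b", "a"))
  expect_identical(sort(r1$retained), sort(r2$retained))
  expect_identical(sort(r1$removed), sort(r2$removed))
})

test_that("Cook's distances match an explicit leave-one-out refit oracle", {
  set.seed(75)
  n <- 30
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n)
  fit <- lm(y ~ x)
  d <- cooks_filter(fit)$distances
  p <- 2
  s2 <- summary(fit)$sigma^2
  X <- model.matrix(fit)
  yhat <- fitted(fit)
  oracle <- vapply(seq_len(n), function(i) {
    refit <- lm(y[-i] ~ x[-i])
    yhat_i <- X %*% coef(refit)
    sum((yhat - yhat_i)^2) / (p * s2)
  }, numeric(1))
  expect_equal(d, oracle, tolerance = 1e-8)
})

test_that("Cook's filter removes a gross outlier and nothing else", {
  set.seed(76)
  x <- c(1:20, 60)
  y <- c(2 * (1:20) + rnorm(20, sd = 0.1), 300)
  fit <- lm(y ~ x)
  res <- cooks_filter(fit)
  expect_identical(res$removed, 21L)

  # clean data: nothing trips the threshold, fit results are untouched
  fit2 <- lm(y[1:20] ~ x[1:20])
  res2 <- cooks_filter(fit2)
  expect_identical(res2$removed, integer())
  expect_identical(res2$retained, 1:20)
})

test_that("when no filter trips, fit_model equals a plain unfiltered fit", {
  tab <- simulate_study(generate_cohort(cohort_config(n = 120), seed = 81), seed = 82)
  std <- standardize_analysis(tab)
  f <- fit_model(model_spec(3), std, ci_method = "wald")
  expect_identical(f$vif_removed, character())
  expect_identical(f$cooks_removed, integer())
  direct <- lm(age ~ tint_z + male + hour_cos_z + education + svrt_z +
                 pal_z + carrier, data = std)
  expect_equal(unname(coef(direct)), f$coefs$estimate)
})
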