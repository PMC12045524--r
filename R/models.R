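#' Specification of the study's five regression models
#'
#' The five pre-specified multivariable models relating Super G performance
#' to Alzheimer-risk factors, each with the full control set:
#'
#' 1. `carrier_logistic` — APOE e4 carrier status ~ performance + age + sex
#'    + hour played + education + svRT + PAL (logistic);
#' 2. `sex_logistic` — male ~ performance + age + hour + education + svRT +
#'    PAL + carrier (logistic);
#' 3. `age_linear` — age ~ performance + sex + hour + education + svRT +
#'    PAL + carrier (linear);
#' 4. `pal_linear` — PAL ~ performance + age + sex + hour + education +
#'    svRT + carrier, plus the sex-by-performance interaction (linear);
#' 5. `pal_adjusted_linear` — as model 4 with the delay-adjusted PAL score
#'    as outcome.
#'
#' Numeric predictors enter z-standardized (so coefficients are per 1 SD);
#' linear outcomes stay on their natural scale (years of age, PAL points),
#' matching how the study reports its betas. Education enters as dummies
#' with "high school diploma" as reference.
#'
#' @param model_id Integer 1-5 or one of the names above.
#' @param performance Which session-mean metric is the performance
#'   predictor: `"tint"`, `"rt"`, `"sr"` or `"tr"`. Defaults per model to
#'   the metric the study emphasizes (RT for the carrier model, TinT
#'   elsewhere).
#' @return A list of class `sg_model_spec` with the outcome, family,
#'   formula and term roles.
#' @examples
#' model_spec(1)$formula
#' model_spec(4, performance = "tint")$formula
#' @export
model_spec <- function(model_id, performance = NULL) {
  names_map <- c(carrier_logistic = 1, sex_logistic = 2, age_linear = 3,
                 pal_linear = 4, pal_adjusted_linear = 5)
  if (is.character(model_id)) model_id <- unname(names_map[model_id])
  if (!model_id %in% 1:5) abort("model_id must be 1-5 or a known model name")
  model_id <- as.integer(model_id)
  if (is.null(performance)) performance <- if (model_id == 1) "rt" else "tint"
  perf_cols <- c(tint = "tint_z", rt = "rt_z", sr = "sr_z", tr = "tr_z")
  if (!performance %in% names(perf_cols)) {
    abort("performance must be one of tint, rt, sr, tr")
  }
  perf <- unname(perf_cols[performance])

  outcome <- switch(model_id, "carrier", "male", "age", "pal_raw", "pal_adjusted")
  family <- if (model_id <= 2) "binomial" else "gaussian"
  controls <- switch(
    model_id,
    c("age_z", "male", "hour_cos_z", "education", "svrt_z", "pal_z"),
    c("age_z", "hour_cos_z", "education", "svrt_z", "pal_z", "carrier"),
    c("male", "hour_cos_z", "education", "svrt_z", "pal_z", "carrier"),
    c("age_z", "male", "hour_cos_z", "education", "svrt_z", "carrier"),
    c("age_z", "male", "hour_cos_z", "education", "svrt_z", "carrier")
  )
  interaction <- model_id >= 4
  rhs <- c(perf, controls, if (interaction) paste0(perf, ":male"))
  structure(
    list(
      model_id = model_id,
      name = names(names_map)[model_id],
      outcome = outcome,
      family = family,
      performance = performance,
      perf_col = perf,
      controls = controls,
      interaction = interaction,
      predictors = rhs,
      formula = reformulate(rhs, response = outcome)
    ),
    class = "sg_model_spec"
  )
}

#' @export
print.sg_model_spec <- function(x, ...) {
  cat(sprintf("<model %d: %s (%s)>\n", x$model_id, x$name, x$family))
  print(x$formula, showEnv = FALSE)
  invisible(x)
}

#' Fit one study model with the study's filtering rules
#'
#' Applies the full inferential recipe to a standardized analysis table:
#' variables with a variance inflation factor above `vif_threshold` are
#' iteratively removed; the model is fit (maximum-likelihood logistic or
#' least-squares linear); observations with Cook's distance above
#' `cooks_threshold` are removed and the model refit once. Coefficients are
#' reported with 95% CIs — profile-likelihood for logistic models (the
#' appropriate interval at this sample size; Wald available by flag),
#' t-based for linear models — and logistic terms additionally as odds
#' ratios.
#'
#' @param spec A [model_spec()] (or an integer passed to it).
#' @param data An `sg_standardized` table from [standardize_analysis()].
#' @param vif_threshold VIF removal threshold (default 5).
#' @param cooks_threshold Cook's distance removal threshold (default 1).
#' @param ci_method `"profile"` (default), `"wald"`, or `"none"` to skip
#'   interval computation (fast, for simulation loops; p-values and
#'   estimates are unaffected).
#' @return An object of class `sg_fit`; see [tidy.sg_fit()] /
#'   [glance.sg_fit()].
#' @examples
#' \donttest{
#' tab <- simulate_study(generate_cohort(cohort_config(n = 80), seed = 1), seed = 2)
#' fit <- fit_model(model_spec(3), standardize_analysis(tab), ci_method = "wald")
#' tidy(fit)
#' }
#' @export
fit_model <- function(spec, data, vif_threshold = 5, cooks_threshold = 1,
                      ci_method = c("profile", "wald", "none")) {
  ci_method <- match.arg(ci_method)
  if (!inherits(spec, "sg_model_spec")) spec <- model_spec(spec)
  needed <- c(spec$outcome, spec$perf_col, spec$controls)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste("data is missing model columns:", paste(missing_cols, collapse = ", ")))
  }
  if (spec$family == "binomial" && !is.logical(data[[spec$outcome]])) {
    abort(sprintf("logistic outcome '%s' must be logical", spec$outcome))
  }
  data <- data[complete.cases(data[, needed]), , drop = FALSE]
  if ("education" %in% names(data)) data$education <- droplevels(data$education)

  # collinearity screen on the main-effect predictors; an interaction is
  # rebuilt afterwards if both parents survived
  main_terms <- c(spec$perf_col, spec$controls)
  vf <- vif_filter(data, main_terms, threshold = vif_threshold)
  rhs <- vf$retained
  if (spec$interaction && all(c(spec$perf_col, "male") %in% rhs)) {
    rhs <- c(rhs, paste0(spec$perf_col, ":male"))
  }
  f <- reformulate(rhs, response = spec$outcome)

  fit1 <- if (spec$family == "binomial") {
    glm(f, family = binomial(), data = data)
  } else {
    lm(f, data = data)
  }
  if (inherits(fit1, "glm") && !fit1$converged) {
    abort(sprintf("model %d did not converge in %d IWLS iterations",
                  spec$model_id, fit1$iter))
  }

  ck <- cooks_filter(fit1, threshold = cooks_threshold)
  if (length(ck$removed)) {
    data_used <- data[ck$retained, , drop = FALSE]
    if ("education" %in% names(data_used)) {
      data_used$education <- droplevels(data_used$education)
    }
    fit <- if (spec$family == "binomial") {
      glm(f, family = binomial(), data = data_used)
    } else {
      lm(f, data = data_used)
    }
  } else {
    data_used <- data
    fit <- fit1
  }

  structure(
    list(
      spec = spec,
      fit = fit,
      formula = f,
      coefs = fit_coef_table(fit, spec$family, ci_method),
      vif_removed = vf$removed,
      vif = vf$vif,
      cooks_distances = ck$distances,
      cooks_removed = ck$removed,
      n_obs = nrow(data_used),
      ci_method = ci_method
    ),
    class = "sg_fit"
  )
}

fit_coef_table <- function(fit, family, ci_method) {
  sm <- summary(fit)$coefficients
  out <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, 1]),
    std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    p.value = unname(sm[, 4])
  )
  ci <- NULL
  if (ci_method == "profile") {
    ci <- tryCatch(
      suppressMessages(suppressWarnings(confint(fit, level = 0.95))),
      error = function(e) NULL
    )
    if (is.null(ci)) ci_method <- "wald"  # quasi-separation fallback
  }
  if (ci_method == "wald") {
    z <- qnorm(0.975)
    ci <- cbind(out$estimate - z * out$std.error,
                out$estimate + z * out$std.error)
  }
  if (!is.null(ci)) {
    if (is.null(dim(ci))) ci <- matrix(ci, nrow = 1)
    out$conf.low <- ci[, 1]
    out$conf.high <- ci[, 2]
  } else {
    out$conf.low <- NA_real_
    out$conf.high <- NA_real_
  }
  if (family == "binomial") {
    out$odds.ratio <- exp(out$estimate)
    out$or.conf.low <- exp(out$conf.low)
    out$or.conf.high <- exp(out$conf.high)
  }
  out
}

#' @export
print.sg_fit <- function(x, ...) {
  cat(sprintf("<Super G model fit: %s, n = %d>\n", x$spec$name, x$n_obs))
  print(x$formula, showEnv = FALSE)
  if (length(x$vif_removed)) {
    cat("removed by VIF:", paste(x$vif_removed, collapse = ", "), "\n")
  }
  if (length(x$cooks_removed)) {
    cat("rows removed by Cook's distance:",
        paste(x$cooks_removed, collapse = ", "), "\n")
  }
  print(x$coefs, n = Inf)
  invisible(x)
}

#' Fit all (or a subset of) the study models
#'
#' @param data An `sg_standardized` analysis table.
#' @param models Integer vector of model ids (1-5).
#' @param ... Passed to [fit_model()].
#' @return A named list of `sg_fit` objects.
#' @export
fit_study_models <- function(data, models = 1:5, ...) {
  fits <- lapply(models, function(id) fit_model(model_spec(id), data, ...))
  names(fits) <- vapply(models, function(id) model_spec(id)$name, character(1))
  fits
}
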