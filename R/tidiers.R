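#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Super G model fit
#'
#' @param x An `sg_fit` from [fit_model()].
#' @param exponentiate Return odds-ratio columns only (logistic fits).
#' @param ... Unused.
#' @return A tibble with one row per model term: estimate, standard error,
#'   statistic, p-value, 95% CI and (for logistic fits) odds ratios.
#' @export
tidy.sg_fit <- function(x, exponentiate = FALSE, ...) {
  out <- x$coefs
  if (exponentiate) {
    if (x$spec$family != "binomial") {
      abort("exponentiate only applies to logistic fits")
    }
    out <- dplyr::transmute(
      out, term = .data$term, odds.ratio = .data$odds.ratio,
      or.conf.low = .data$or.conf.low, or.conf.high = .data$or.conf.high,
      p.value = .data$p.value
    )
  }
  out
}

#' @rdname tidy.sg_fit
#' @return For `glance()`: a one-row tibble with the model id, sample size
#'   after filtering, counts of VIF-removed terms and Cook's-removed rows,
#'   and the fit criterion (AIC for logistic, R^2 for linear).
#' @export
glance.sg_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$spec$model_id,
    model = x$spec$name,
    family = x$spec$family,
    n_obs = x$n_obs,
    n_vif_removed = length(x$vif_removed),
    n_cooks_removed = length(x$cooks_removed),
    ci_method = x$ci_method,
    aic = if (x$spec$family == "binomial") stats::AIC(x$fit) else NA_real_,
    r.squared = if (x$spec$family == "gaussian")
      summary(x$fit)$r.squared else NA_real_
  )
}
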