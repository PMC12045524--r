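#' Parameters of the bang-coast-bang synthetic participant
#'
#' Synthetic participants play an open-loop plan on every attempt: exit the
#' start planet around `t_go_mean`, thrust right for about `tau_right`
#' seconds, coast, then brake left for about `rho * tau_right` seconds
#' starting near `t_rev_mean`. Each attempt perturbs the planned exit time,
#' both press durations and the reversal onset with independent Gaussian
#' jitter of SD `timing_sd`, and with probability `lapse_prob` the attempt is
#' an off-plan lapse with no presses at all. Together these span the four
#' skill metrics: `t_go_mean` drives response time, `t_rev_mean` the time of
#' reversal, `rho` the scaling ratio, and `timing_sd` (landing accuracy)
#' time in target.
#'
#' @param t_go_mean Planned exit time from trial start, seconds; should be
#'   at or above the hold duration or the trial will systematically reset.
#' @param tau_right Planned right-press (thrust) duration, seconds.
#' @param rho Braking ratio: planned left-press duration is `rho * tau_right`.
#' @param t_rev_mean Planned left-press onset from trial start, seconds
#'   (floored at the end of the right press when realized).
#' @param timing_sd Per-attempt Gaussian jitter SD, seconds.
#' @param lapse_prob Probability an attempt makes no presses.
#'
#' @return A list of class `sg_controller_params`.
#' @export
controller_params <- function(t_go_mean = 1.70,
                              tau_right = sqrt(0.5),
                              rho = 1.0,
                              t_rev_mean = 1.70 + sqrt(0.5),
                              timing_sd = 0.055,
                              lapse_prob = 0.02) {
  p <- list(t_go_mean = t_go_mean, tau_right = tau_right, rho = rho,
            t_rev_mean = t_rev_mean, timing_sd = timing_sd,
            lapse_prob = lapse_prob)
  validate_controller_params(p)
  structure(p, class = "sg_controller_params")
}

validate_controller_params <- function(p) {
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1)))) {
    abort("controller params must be finite numeric scalars")
  }
  if (p$tau_right < 0 || p$timing_sd < 0 || p$rho < 0) {
    abort("tau_right, rho and timing_sd must be non-negative")
  }
  if (p$lapse_prob < 0 || p$lapse_prob > 1) {
    abort("lapse_prob must lie in [0, 1]")
  }
  invisible(p)
}

#' Turn controller parameters into a playable policy
#'
#' @param params A [controller_params()].
#' @return An object of class `sg_policy` usable with [run_trial()] /
#'   [run_session()]. Attempt-level randomness is drawn from the ambient R
#'   RNG stream, so simulations are reproducible under `set.seed()`.
#' @examples
#' pol <- make_policy(controller_params(timing_sd = 0))
#' run_trial(task_config(), pol)$success
#' @export
make_policy <- function(params) {
  validate_controller_params(params)
  structure(list(kind = "plan", params = params), class = "sg_policy")
}

# ---- covariate links -------------------------------------------------------

#' One linked controller parameter
#'
#' @param intercept Baseline value of the parameter.
#' @param coef Named numeric vector of coefficients on the standardized
#'   covariates `age_z`, `male`, `carrier`, `pal_z`, `pal_z:male`, `skill_z`.
#' @param sd Between-participant Gaussian SD around the linear predictor.
#' @param lower,upper Clamping bounds keeping realized parameters valid.
#' @return A list describing the link for one parameter.
#' @export
link_term <- function(intercept, coef = numeric(), sd = 0,
                      lower = -Inf, upper = Inf) {
  allowed <- c("age_z", "male", "carrier", "pal_z", "pal_z:male", "skill_z")
  if (length(coef) && (is.null(names(coef)) || !all(names(coef) %in% allowed))) {
    abort(paste("link coefficients must be named among:",
                paste(allowed, collapse = ", ")))
  }
  list(intercept = intercept, coef = coef, sd = sd, lower = lower, upper = upper)
}

#' Generative link from covariates to gameplay parameters
#'
#' Maps each participant's (standardized) covariates to their controller
#' parameters, giving the generative model that the downstream regressions
#' must recover. The defaults encode the study's association structure:
#' older age inflates timing jitter (worse time in target), male sex and a
#' latent skill trait reduce it, and APOE e4 carriers plan an earlier exit
#' (faster response time). The latent `skill_z` trait also raises PAL in
#' males only (see [cohort_config()]), creating the sex-dependent PAL-TinT
#' coupling. Effect sizes are calibrated to standardized effects of roughly
#' 0.5-1 SD on the session-mean metrics so that sign recovery is testable at
#' a few hundred participants.
#'
#' @param t_go_mean,tau_right,rho,timing_sd,lapse_prob [link_term()]
#'   objects, one per controller parameter.
#' @param t_rev_gap [link_term()] for the planned coast gap (seconds)
#'   between the end of the thrust press and the braking onset; the
#'   participant's absolute reversal plan is
#'   `t_rev_mean = t_go_mean + tau_right + t_rev_gap`, so reversal timing
#'   tracks each participant's own exit plan.
#' @return A list of class `sg_covariate_link`.
#' @seealso [zero_effect_link()] for the null link used in type-I
#'   calibration.
#' @export
covariate_link <- function(
    t_go_mean = link_term(1.70, c(carrier = -0.10), sd = 0.10,
                          lower = 1.3, upper = 3.5),
    tau_right = link_term(sqrt(0.5), sd = 0.008, lower = 0.05, upper = 1.4),
    rho = link_term(1.0, sd = 0.015, lower = 0.05, upper = 3),
    t_rev_gap = link_term(0.0, sd = 0.02, lower = -0.3, upper = 1.0),
    timing_sd = link_term(0.055,
                          c(age_z = 0.010, male = -0.018, skill_z = -0.010),
                          sd = 0.008, lower = 0.002, upper = 0.25),
    lapse_prob = link_term(0.02, lower = 0, upper = 1)) {
  structure(
    list(t_go_mean = t_go_mean, tau_right = tau_right, rho = rho,
         t_rev_gap = t_rev_gap, timing_sd = timing_sd,
         lapse_prob = lapse_prob),
    class = "sg_covariate_link"
  )
}

#' @rdname covariate_link
#' @details `zero_effect_link()` keeps the intercepts and between-participant
#' heterogeneity of the default link but zeroes every covariate coefficient,
#' so gameplay is independent of all covariates: the null model for type-I
#' error calibration.
#' @export
zero_effect_link <- function() {
  link <- covariate_link()
  for (nm in names(link)) link[[nm]]$coef <- numeric()
  link
}

#' Realize per-participant controller parameters from covariates
#'
#' Computes, for every cohort row, `intercept + sum(coef * covariate) +
#' participant noise` for each controller parameter and clamps the result to
#' its valid range. Clamping is logged in the `"clamping"` attribute (and
#' raises a warning if it alters more than 1% of participants for any
#' parameter, which would distort the generative effect sizes).
#'
#' @param cohort A cohort tibble from [generate_cohort()] (needs `age`,
#'   `sex`, `apoe_genotype`, `pal_raw`; `skill_z` if the link uses it).
#' @param link A [covariate_link()].
#' @param seed Optional integer seed for the participant-level noise.
#'
#' @return A tibble with one row per participant and one column per
#'   controller parameter, with attribute `"clamping"` (tibble: `param`,
#'   `n_clamped`).
#' @export
link_params <- function(cohort, link = covariate_link(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  need <- c("age", "sex", "apoe_genotype", "pal_raw")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    abort(paste("cohort is missing covariates:", paste(missing_cols, collapse = ", ")))
  }
  male <- as.numeric(cohort$sex == "male")
  z0 <- function(x) {
    if (length(x) > 1 && sd(x) > 0) as.numeric(scale(x)) else rep(0, length(x))
  }
  covs <- list(
    age_z = z0(cohort$age),
    male = male,
    carrier = as.numeric(carrier_status(cohort$apoe_genotype)),
    pal_z = z0(cohort$pal_raw),
    skill_z = if ("skill_z" %in% names(cohort)) cohort$skill_z else NULL
  )
  covs[["pal_z:male"]] <- covs$pal_z * male

  vals <- clamped <- vector("list", length(link))
  names(vals) <- names(link)
  for (param in names(link)) {
    term <- link[[param]]
    mu <- rep(term$intercept, n)
    for (nm in names(term$coef)) {
      if (is.null(covs[[nm]])) {
        abort(sprintf("link for '%s' needs covariate '%s' absent from the cohort",
                      param, nm))
      }
      mu <- mu + term$coef[[nm]] * covs[[nm]]
    }
    raw <- mu + rnorm(n) * term$sd
    vals[[param]] <- pmin(pmax(raw, term$lower), term$upper)
    clamped[[param]] <- sum(raw < term$lower | raw > term$upper)
  }
  out <- tibble::as_tibble(vals)
  if ("t_rev_gap" %in% names(out)) {
    out$t_rev_mean <- out$t_go_mean + out$tau_right + out$t_rev_gap
    out$t_rev_gap <- NULL
  }
  log <- tibble::tibble(param = names(link),
                        n_clamped = unlist(clamped, use.names = FALSE))
  attr(out, "clamping") <- log
  # the 1% rule is only meaningful at cohort scale; small runs are logged
  # via the attribute without a warning
  noisy <- log$n_clamped > pmax(0.01 * n, 9)
  if (n >= 200 && any(noisy)) {
    warn(paste("covariate link clamped more than 1% of participants for:",
               paste(log$param[noisy], collapse = ", ")))
  }
  out
}
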