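#' @rdname cohort_config
#' @export
education_levels <- function() {
  c("high school diploma", "some college", "four-year degree",
    "postgraduate degree")
}

#' Configuration of the synthetic MindCrowd-like cohort
#'
#' Defaults reproduce the marginal structure of the study sample: 54 adults
#' aged 45+ (mean 62.4, SD 7.4 years), 39 of 54 female, APOE genotype counts
#' 2/3: 2, 3/3: 29, 2/4: 4, 3/4: 16, 4/4: 3 (23 e4 carriers), a highly
#' educated distribution, a paired-associates-learning (PAL) score on 0-36
#' with age and sex effects, a right-skewed (log-normal) median simple
#' visual reaction time, an afternoon-centered hour of play on the 24-hour
#' clock, and a 5.9 (SD 1.4) year delay between PAL and gameplay.
#'
#' PAL is generated on a latent Gaussian scale
#' `intercept + pal_age * age_z + pal_male * male + pal_male_skill * male *
#' skill_z + noise`, then rounded and clipped to 0-36. `skill_z` is a latent
#' standard-normal motor-skill trait stored in the cohort table; the default
#' [covariate_link()] lets it reduce gameplay timing jitter, so PAL and time
#' in target are coupled in males only — the generative analogue of the
#' sex-by-TinT interaction probed by model 4.
#'
#' @param n Cohort size.
#' @param age_mean,age_sd,age_min Age distribution (years), truncated below
#'   at `age_min`.
#' @param female_prop Proportion female.
#' @param genotype_probs Named probabilities over APOE genotypes `a/b`.
#' @param education_probs Named probabilities over [education_levels()].
#' @param pal_intercept,pal_age,pal_male,pal_male_skill,pal_sd Latent-scale
#'   PAL generative coefficients (points; `pal_age` per SD of age).
#' @param svrt_meanlog,svrt_sdlog Log-normal parameters of median svRT (ms).
#' @param hour_mean,hour_sd Hour-of-day distribution, truncated to `[0, 24)`
#'   and floored to the integer hour.
#' @param delay_mean,delay_sd Years between PAL and gameplay, truncated at 0.
#' @param sampling `"iid"` draws categorical covariates independently;
#'   `"exact"` fixes their margins to largest-remainder counts (reproducing
#'   the study's integer table at `n = 54`) and shuffles assignments.
#'
#' @return A list of class `sg_cohort_config`.
#' @export
cohort_config <- function(n = 54,
                          age_mean = 62.39, age_sd = 7.4, age_min = 45,
                          female_prop = 39 / 54,
                          genotype_probs = c("2/2" = 0, "2/3" = 2, "3/3" = 29,
                                             "2/4" = 4, "3/4" = 16, "4/4" = 3) / 54,
                          education_probs = c("high school diploma" = 1,
                                              "some college" = 9,
                                              "four-year degree" = 21,
                                              "postgraduate degree" = 23) / 54,
                          pal_intercept = 22.1, pal_age = -2, pal_male = -4,
                          pal_male_skill = 5, pal_sd = 6.5,
                          svrt_meanlog = log(400), svrt_sdlog = 0.19,
                          hour_mean = 14.1, hour_sd = 4.3,
                          delay_mean = 5.9, delay_sd = 1.4,
                          sampling = c("iid", "exact")) {
  sampling <- match.arg(sampling)
  if (n < 1) abort("n must be at least 1")
  if (abs(sum(genotype_probs) - 1) > 1e-9 || any(genotype_probs < 0)) {
    abort("genotype_probs must be non-negative and sum to 1")
  }
  if (abs(sum(education_probs) - 1) > 1e-9 || any(education_probs < 0)) {
    abort("education_probs must be non-negative and sum to 1")
  }
  if (!all(names(education_probs) %in% education_levels())) {
    abort("education_probs must be named with the standard education levels")
  }
  if (female_prop < 0 || female_prop > 1) abort("female_prop must be in [0, 1]")
  structure(as.list(environment()), class = "sg_cohort_config")
}

# deterministic largest-remainder apportionment of n among probabilities
apportion <- function(n, probs) {
  quota <- n * probs
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    frac <- quota - counts
    top <- order(frac, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  counts
}

rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  u <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(u, mean, sd)
}

draw_categorical <- function(n, probs, sampling) {
  if (sampling == "exact") {
    counts <- apportion(n, probs)
    sample(rep(names(probs), counts))
  } else {
    sample(names(probs), n, replace = TRUE, prob = probs)
  }
}

#' Generate a synthetic cohort
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per participant: `participant_id`, `age`,
#'   `sex`, `apoe_genotype`, `education`, `skill_z` (latent motor-skill
#'   trait), `pal_raw`, `svrt_median`, `hour_played`, `years_since_pal`.
#' @examples
#' cohort <- generate_cohort(cohort_config(sampling = "exact"), seed = 1)
#' table(carrier_status(cohort$apoe_genotype))
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  if (!inherits(config, "sg_cohort_config")) abort("config must be a cohort_config()")
  if (!is.null(seed)) set.seed(seed)
  n <- config$n

  age <- rtnorm(n, config$age_mean, config$age_sd, lower = config$age_min)
  sex <- draw_categorical(
    n, c(female = config$female_prop, male = 1 - config$female_prop),
    config$sampling
  )
  genotype <- draw_categorical(n, config$genotype_probs, config$sampling)
  education <- draw_categorical(n, config$education_probs, config$sampling)
  skill_z <- rnorm(n)

  age_z <- if (n > 1 && sd(age) > 0) as.numeric(scale(age)) else rep(0, n)
  male <- as.numeric(sex == "male")
  pal_latent <- config$pal_intercept + config$pal_age * age_z +
    config$pal_male * male + config$pal_male_skill * male * skill_z +
    rnorm(n) * config$pal_sd
  pal_raw <- pmin(pmax(round(pal_latent), 0), 36)

  svrt <- rlnorm(n, config$svrt_meanlog, config$svrt_sdlog)
  hour <- floor(rtnorm(n, config$hour_mean, config$hour_sd, lower = 0, upper = 24))
  delay <- rtnorm(n, config$delay_mean, config$delay_sd, lower = 0)

  tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    age = age,
    sex = sex,
    apoe_genotype = genotype,
    education = factor(education, levels = education_levels()),
    skill_z = skill_z,
    pal_raw = as.integer(pal_raw),
    svrt_median = svrt,
    hour_played = as.integer(pmin(hour, 23)),
    years_since_pal = delay
  )
}

#' Simulate the full study: cohort gameplay to analysis table
#'
#' For every participant, realizes controller parameters from their
#' covariates via the link, plays a full session through the compiled
#' engine, and joins the session-mean metrics back onto the covariates.
#' The result is the analysis table every regression model consumes. Fully
#' reproducible given `seed`.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param link A [covariate_link()].
#' @param task A [task_config()].
#' @param seed Optional integer seed.
#' @return The cohort tibble with appended columns `mean_sr`, `mean_tr`,
#'   `mean_tint`, `mean_rt`, `mean_rt_go` (ms), `n_success` and `n_resets`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 3), seed = 1)
#' simulate_study(cohort, seed = 1)[, c("participant_id", "mean_tint")]
#' @export
simulate_study <- function(cohort, link = covariate_link(),
                           task = task_config(), seed = NULL) {
  validate_task_config(task)
  if (!is.null(seed)) set.seed(seed)
  params <- link_params(cohort, link)
  pm <- as.matrix(params[, c("t_go_mean", "tau_right", "rho", "t_rev_mean",
                             "timing_sd", "lapse_prob")])
  m <- sg_cohort_metrics_cpp(pm, unclass(task))
  dplyr::bind_cols(
    cohort,
    tibble::tibble(
      mean_sr = m[, "mean_sr"],
      mean_tr = m[, "mean_tr"] * 1000,
      mean_tint = m[, "mean_tint"] * 1000,
      mean_rt = m[, "mean_rt"] * 1000,
      mean_rt_go = m[, "mean_rt_go"] * 1000,
      n_success = as.integer(m[, "n_success"]),
      n_resets = as.integer(m[, "n_resets"])
    )
  )
}
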