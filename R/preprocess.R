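#' APOE e4 carrier status from a genotype string
#'
#' Carriers are individuals with one or two copies of the e4 allele;
#' noncarriers have zero copies. This partitions the six genotypes seen in
#' the study into carriers (2/4, 3/4, 4/4) and noncarriers (2/2, 2/3, 3/3).
#'
#' @param apoe_genotype Character vector of genotypes `"a/b"` with alleles
#'   in `{2, 3, 4}`.
#' @return A logical vector: `TRUE` for carriers.
#' @examples
#' carrier_status(c("3/3", "2/4", "4/4", "2/2"))
#' @export
carrier_status <- function(apoe_genotype) {
  apoe_genotype <- as.character(apoe_genotype)
  ok <- grepl("^[234]/[234]$", apoe_genotype)
  if (anyNA(apoe_genotype) || !all(ok)) {
    bad <- unique(apoe_genotype[is.na(apoe_genotype) | !ok])
    abort(paste0("malformed APOE genotype(s): ",
                 paste(bad, collapse = ", "),
                 " (expected \"a/b\" with alleles 2, 3 or 4)"))
  }
  grepl("4", apoe_genotype, fixed = TRUE)
}

#' Circular encoding of hour of day
#'
#' `cos(2 * pi * hour / 24)`: maps the 24-hour clock onto a cosine so that
#' adjacent hours 23 and 0/1 sit close together instead of 23 units apart.
#'
#' @param hour Numeric hour in `[0, 24)`.
#' @return `cos(2 * pi * hour / 24)`.
#' @examples
#' cosine_hour(c(0, 12, 23, 1))
#' @export
cosine_hour <- function(hour) {
  if (anyNA(hour) || any(hour < 0 | hour >= 24)) {
    abort("hour must lie in [0, 24)")
  }
  cos(2 * pi * hour / 24)
}

#' Delay-adjusted PAL score
#'
#' Projects a historical paired-associates-learning score forward to the
#' gameplay date using the expected decline of 0.2 points per year between
#' the two measurements: `pal_raw - 0.2 * years_since_pal`.
#'
#' @param pal_raw PAL score (0-36) at the original measurement.
#' @param years_since_pal Non-negative years between PAL and gameplay.
#' @return The adjusted score (the expected decline is subtracted; the
#'   direction is also recorded in the `"adjustment"` attribute so the
#'   opposite convention is one sign flip away).
#' @examples
#' adjust_pal(20, 5.9)
#' @export
adjust_pal <- function(pal_raw, years_since_pal) {
  if (any(years_since_pal < 0, na.rm = TRUE)) abort("years_since_pal must be >= 0")
  out <- pal_raw - 0.2 * years_since_pal
  attr(out, "adjustment") <- "subtract 0.2 points per year from the historical score"
  out
}

# analysis-table numeric columns and their standardized names
z_column_map <- c(
  age = "age_z", svrt_median = "svrt_z", pal_raw = "pal_z",
  pal_adjusted = "pal_adj_z", hour_cos = "hour_cos_z",
  mean_tint = "tint_z", mean_rt = "rt_z", mean_sr = "sr_z", mean_tr = "tr_z"
)

#' z-score a numeric vector
#'
#' Centered at the mean and divided by the `n - 1` standard deviation.
#' @param x Numeric vector with positive SD.
#' @return The standardized vector.
#' @export
z_score <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("cannot standardize a zero-variance vector")
  (x - mean(x)) / s
}

#' Standardize an analysis table for modelling
#'
#' Applies the study's variable constructions in one step: codes `male` and
#' `carrier` as logicals (`TRUE` = male / e4 carrier), builds the
#' delay-adjusted PAL score, replaces hour of day by its cosine transform,
#' orders education with "high school diploma" as the reference level, and
#' z-standardizes every numeric analysis variable (age, svRT, PAL raw and
#' adjusted, cosine hour, and the session-mean Super G metrics present in
#' the table). Standardization parameters are stored in the `"transforms"`
#' attribute so [unstandardize()] can invert the mapping.
#'
#' @param data An analysis tibble from [simulate_study()] (or any table with
#'   the same covariate columns).
#' @return The table with appended `male`, `carrier`, `pal_adjusted`,
#'   `hour_cos` and `*_z` columns; class `sg_standardized`.
#' @export
standardize_analysis <- function(data) {
  out <- data
  out$male <- out$sex == "male"
  out$carrier <- carrier_status(out$apoe_genotype)
  if (all(c("pal_raw", "years_since_pal") %in% names(out))) {
    out$pal_adjusted <- as.numeric(adjust_pal(out$pal_raw, out$years_since_pal))
  }
  if ("hour_played" %in% names(out)) out$hour_cos <- cosine_hour(out$hour_played)
  if ("education" %in% names(out)) {
    out$education <- factor(out$education, levels = education_levels())
  }
  vars <- names(z_column_map)[names(z_column_map) %in% names(out)]
  transforms <- tibble::tibble(
    variable = vars,
    z_name = unname(z_column_map[vars]),
    mean = vapply(vars, function(v) mean(out[[v]]), numeric(1)),
    sd = vapply(vars, function(v) sd(out[[v]]), numeric(1))
  )
  zero <- transforms$variable[!is.finite(transforms$sd) | transforms$sd == 0]
  if (length(zero)) {
    abort(paste("cannot standardize zero-variance column(s):",
                paste(zero, collapse = ", ")))
  }
  for (i in seq_len(nrow(transforms))) {
    out[[transforms$z_name[i]]] <-
      (out[[transforms$variable[i]]] - transforms$mean[i]) / transforms$sd[i]
  }
  attr(out, "transforms") <- transforms
  class(out) <- c("sg_standardized", class(out))
  out
}

#' @rdname standardize_analysis
#' @details `unstandardize()` reconstructs each original column from its
#' z-scored version using the stored transform parameters (a round-trip
#' identity up to floating precision).
#' @export
unstandardize <- function(data) {
  tr <- attr(data, "transforms")
  if (is.null(tr)) abort("data carries no transforms attribute")
  out <- data
  for (i in seq_len(nrow(tr))) {
    out[[tr$variable[i]]] <- out[[tr$z_name[i]]] * tr$sd[i] + tr$mean[i]
  }
  out
}

#' Covariate-adjusted empirical percentile against a reference cohort
#'
#' Places a participant's score within the reference distribution of
#' participants who share their age decade, sex and education level
#' (midpoint/midrank convention for ties, so a value equal to the stratum
#' median scores the 50th percentile and a value above every reference
#' value scores the 100th). When the full stratum is empty in the
#' reference, falls back to the sex-by-education stratum with a warning.
#' This is a stratified stand-in for norm tables computed on the full
#' MindCrowd cohort, which are not public.
#'
#' @param value The participant's score.
#' @param covariates A one-row data frame with `age`, `sex`, `education`.
#' @param reference A cohort tibble containing `variable` plus the
#'   stratification covariates.
#' @param variable Name of the score column in `reference`.
#' @return The percentile (0-100).
#' @export
percentile_vs_reference <- function(value, covariates, reference, variable) {
  if (!variable %in% names(reference)) {
    abort(sprintf("reference has no column '%s'", variable))
  }
  decade <- function(a) floor(a / 10)
  stratum <- reference[
    decade(reference$age) == decade(covariates$age) &
      reference$sex == covariates$sex &
      as.character(reference$education) == as.character(covariates$education),
  ]
  if (nrow(stratum) == 0) {
    warn("empty age-decade stratum; falling back to sex x education")
    stratum <- reference[
      reference$sex == covariates$sex &
        as.character(reference$education) == as.character(covariates$education),
    ]
    if (nrow(stratum) == 0) abort("no matching reference stratum")
  }
  ref <- stratum[[variable]]
  100 * (sum(ref < value) + 0.5 * sum(ref == value)) / length(ref)
}
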