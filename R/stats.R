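#' Wilcoxon rank-sum comparison of two groups
#'
#' Used for carrier vs noncarrier group comparisons, where the unequal group
#' sizes argue against parametric tests. The statistic `W` is the rank sum
#' of the first group minus its minimum (the Mann-Whitney U of `x`). The
#' p-value is exact (full enumeration) when the combined sample is small
#' (`n1 + n2 <= 20`) and tie-free, and otherwise uses the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples.
#' @return A one-row tibble: `statistic` (W), `p.value`, `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    warn("all observations are tied; p-value is 1 by convention")
    return(tibble::tibble(statistic = length(x) * length(y) / 2,
                          p.value = 1, method = "degenerate"))
  }
  exact <- (length(x) + length(y)) <= 20 && !any(duplicated(pooled))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(ht$statistic),
    p.value = ht$p.value,
    method = if (exact) "exact" else "normal approximation"
  )
}

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson's chi-square with one degree of freedom; with `yates = TRUE`
#' each `|O - E|` is reduced by 0.5 (floored at zero) before squaring,
#' which is what makes the study's sex-by-carrier table come out at
#' exactly zero.
#'
#' @param table A 2x2 matrix of non-negative counts with positive margins.
#' @param yates Apply the continuity correction?
#' @return A one-row tibble: `statistic`, `df`, `p.value`.
#' @examples
#' chi_square_2x2(matrix(c(6, 9, 17, 22), 2), yates = TRUE)
#' @export
chi_square_2x2 <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("table must be 2x2")
  if (any(table < 0)) abort("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("undefined statistic: a margin of the table is zero")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
  tibble::tibble(statistic = unname(ht$statistic), df = 1L,
                 p.value = ht$p.value)
}

#' Cohen's d for two independent groups
#'
#' Mean difference divided by the pooled standard deviation (pooled with
#' `n1 + n2 - 2` degrees of freedom).
#'
#' @param x,y Numeric samples with at least two values each.
#' @return The effect size `d` (positive when `x` has the larger mean);
#'   `NA` with a warning when the pooled SD is zero.
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("each sample needs >= 2 values")
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    warn("zero pooled SD; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Express an odds ratio as a percent change in odds
#'
#' An OR below 1 is reported as the percent reduction in odds per +1 SD of
#' the predictor (equivalently, the percent increase in odds of the
#' complementary outcome — the reading used for the study's OR of 0.12,
#' reported as an 88% shift); an OR above 1 as the percent increase.
#'
#' @param or_value A positive odds ratio.
#' @return The percent change.
#' @examples
#' or_to_percent_change(0.12)
#' or_to_percent_change(2.5)
#' @export
or_to_percent_change <- function(or_value) {
  if (any(or_value <= 0)) abort("odds ratios must be positive")
  ifelse(or_value < 1, 100 * (1 - or_value), 100 * (or_value - 1))
}
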