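#' Variance inflation factors and iterative collinearity filtering
#'
#' `vif_filter()` expands the chosen predictors into a model matrix and
#' computes a variance inflation factor per model term. Single-column terms
#' get the classical `VIF_j = 1 / (1 - R2_j)` from regressing column `j` on
#' all other columns; multi-column terms (factors such as education) get the
#' generalized VIF of Fox & Monette, which is invariant to the factor's
#' dummy coding. Terms are removed iteratively, worst first, while any term
#' violates the threshold; the comparison uses `GVIF^(1/(2 df))` against
#' `sqrt(threshold)`, which for a 1-df term is exactly the textbook
#' `VIF > threshold` rule. A perfectly collinear term (infinite VIF) always
#' ranks first, so a duplicated predictor loses exactly one copy.
#'
#' @param data A data frame containing the predictors.
#' @param predictors Character vector of predictor (term) names; at least 2.
#' @param threshold VIF above which a term is removed (study rule: 5).
#' @return A list with `retained` and `removed` term names and `vif`, a
#'   tibble of the final per-term (G)VIFs (`term`, `df`, `gvif`,
#'   `gvif_adj = gvif^(1/(2 df))`).
#' @export
vif_filter <- function(data, predictors, threshold = 5) {
  if (length(predictors) < 2) abort("need at least two predictors")
  missing_cols <- setdiff(predictors, names(data))
  if (length(missing_cols)) {
    abort(paste("predictors absent from data:", paste(missing_cols, collapse = ", ")))
  }
  retained <- predictors
  removed <- character()
  crit <- sqrt(threshold)
  repeat {
    if (length(retained) < 2) break
    vifs <- term_vifs(data, retained)
    worst <- which.max(vifs$gvif_adj)
    if (is.finite(vifs$gvif_adj[worst]) && vifs$gvif_adj[worst] <= crit) break
    removed <- c(removed, vifs$term[worst])
    retained <- setdiff(retained, vifs$term[worst])
  }
  final <- if (length(retained) >= 1) term_vifs(data, retained) else
    tibble::tibble(term = character(), df = integer(),
                   gvif = numeric(), gvif_adj = numeric())
  list(retained = retained, removed = removed, vif = final)
}

# per-term generalized VIFs: det(R_term) * det(R_rest) / det(R_full) on the
# correlation matrix of the centered model-matrix columns
term_vifs <- function(data, terms) {
  f <- reformulate(backtick(terms))
  data <- droplevels(as.data.frame(data)[, terms, drop = FALSE])
  mm <- model.matrix(f, data = data)
  assign <- attr(mm, "assign")
  keep <- assign != 0
  mm <- mm[, keep, drop = FALSE]
  assign <- assign[keep]
  term_labels <- attr(stats::terms(f, data = data), "term.labels")
  R <- suppressWarnings(stats::cor(mm))
  if (anyNA(R)) abort("cannot compute VIFs: a predictor column is constant")
  det_full <- det(R)
  out <- lapply(unique(assign), function(a) {
    idx <- which(assign == a)
    num <- det(R[idx, idx, drop = FALSE]) *
      det(R[-idx, -idx, drop = FALSE])
    gvif <- if (det_full <= 1e-12 * num || det_full <= 0) Inf else num / det_full
    df <- length(idx)
    tibble::tibble(term = term_labels[a], df = df, gvif = gvif,
                   gvif_adj = gvif^(1 / (2 * df)))
  })
  dplyr::bind_rows(out)
}

backtick <- function(x) {
  ifelse(grepl("[:]", x), x, sprintf("`%s`", x))
}

#' Cook's-distance outlier filtering
#'
#' Computes the Cook's distance of every observation of a fitted linear or
#' logistic model (the standard closed form for linear models; the one-step
#' approximation for GLMs) and flags rows whose distance exceeds the
#' threshold for removal. Saturated rows (leverage 1) have infinite
#' distance and are always flagged.
#'
#' @param fit An `lm` or `glm` object.
#' @param threshold Distance above which a row is removed (study rule: 1).
#' @return A list with `distances`, integer `removed` row positions and
#'   `retained` row positions.
#' @export
cooks_filter <- function(fit, threshold = 1) {
  d <- cooks.distance(fit)
  h <- lm.influence(fit, do.coef = FALSE)$hat
  d[h >= 1 - 1e-12] <- Inf
  removed <- which(d > threshold)
  list(
    distances = unname(d),
    removed = as.integer(removed),
    retained = setdiff(seq_along(d), removed)
  )
}
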