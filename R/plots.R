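#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient (forest) plot of a fitted study model
#'
#' Logistic fits are drawn on the odds-ratio scale (log axis, reference
#' line at 1); linear fits on the coefficient scale (reference at 0).
#'
#' @param object An `sg_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sg_fit <- function(object, ...) {
  co <- dplyr::filter(object$coefs, .data$term != "(Intercept)")
  logistic <- object$spec$family == "binomial"
  if (logistic) {
    co <- dplyr::mutate(co, est = .data$odds.ratio,
                        lo = .data$or.conf.low, hi = .data$or.conf.high)
    ref <- 1
    lab <- "odds ratio per 1 SD (95% CI)"
  } else {
    co <- dplyr::mutate(co, est = .data$estimate,
                        lo = .data$conf.low, hi = .data$conf.high)
    ref <- 0
    lab <- "coefficient per 1 SD (95% CI)"
  }
  p <- ggplot2::ggplot(co, ggplot2::aes(x = .data$est,
                                        y = stats::reorder(.data$term, .data$est))) +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::labs(x = lab, y = NULL, title = object$spec$name)
  if (logistic) p <- p + ggplot2::scale_x_log10()
  p
}

#' Cursor trajectory of one trial
#'
#' Position against time for every attempt of the trial, with the target
#' band, the go cue, and reset/landing events marked.
#'
#' @param log An `sg_trial_log`.
#' @param config The [task_config()] the log was produced under.
#' @return A ggplot.
#' @export
plot_trial <- function(log, config) {
  s <- log$samples
  p <- ggplot2::ggplot(s, ggplot2::aes(.data$t, .data$x,
                                       group = .data$attempt,
                                       colour = factor(.data$attempt))) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = config$planet_distance - config$planet_radius,
                      ymax = config$planet_distance + config$planet_radius,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = c(-config$planet_radius, config$planet_radius),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_vline(xintercept = config$hold_duration,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from trial start (s)", y = "position (screen units)",
                  colour = "attempt",
                  title = sprintf("trial %d: %s", log$trial_index,
                                  if (log$success) "landed" else "failed"))
  p
}

#' Within-session course of the skill metrics
#'
#' Time in target per trial across the session, with successes marked —
#' the trial-by-trial picture behind the session-mean metrics.
#'
#' @param metrics A per-trial metrics tibble from [session_metrics()].
#' @return A ggplot.
#' @export
plot_session_metrics <- function(metrics) {
  ggplot2::ggplot(metrics, ggplot2::aes(.data$trial_index, .data$tint_ms)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$success)) +
    ggplot2::labs(x = "trial", y = "time in target (ms)", colour = "landed")
}
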