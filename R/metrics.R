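#' Extract the four Super G performance variables from one trial log
#'
#' Computes, on the trial's final attempt (the post-reset timeline, if any
#' early-exit resets occurred):
#'
#' * `sr` — scaling ratio: total left-press time over total right-press time
#'   within the movement window (undefined when no right press occurred);
#' * `tr_ms` — time of reversal: onset of the first left press after the go
#'   cue, on the absolute trial clock;
#' * `tint_ms` — time in target: cumulative sampled time the cursor spends
#'   within the target planet's radius during the movement window (accrues
#'   on failed trials too);
#' * `rt_ms` — response time: the first sample at which the cursor is
#'   outside the start planet's radius after the go cue, on the absolute
#'   trial clock (so it includes the 1.5 s hold); `rt_go_ms` is the same
#'   measured from the go cue.
#'
#' Metrics that do not occur on a trial (no movement, no reversal) are `NA`
#' rather than zero, and are later excluded from that metric's session mean.
#'
#' @param log An `sg_trial_log` from [run_trial()].
#' @param config The [task_config()] the log was produced under.
#' @return A one-row tibble: `trial_index`, `sr`, `tr_ms`, `tint_ms`,
#'   `rt_ms`, `rt_go_ms`, `success`, `resets`.
#' @export
trial_metrics <- function(log, config) {
  if (!inherits(log, "sg_trial_log")) abort("log must be an sg_trial_log")
  s <- log$samples
  final <- s[s$attempt == max(s$attempt), , drop = FALSE]
  t <- final$t
  if (is.unsorted(t, strictly = TRUE)) {
    abort("malformed log: sample times must be strictly increasing")
  }
  dt <- 1 / config$sample_rate
  if (length(t) > 1 && any(abs(diff(t) - dt) > 1e-9)) {
    abort("malformed log: samples must be evenly spaced at 1/sample_rate")
  }
  hold <- config$hold_duration
  win_end <- hold + config$movement_window
  in_window <- t >= hold & t < win_end

  n_right <- sum(final$key_right & in_window)
  n_left <- sum(final$key_left & in_window)
  sr <- if (n_right > 0) n_left / n_right else NA_real_

  kl <- final$key_left
  edge <- c(FALSE, kl[-1] & !kl[-length(kl)]) & in_window
  tr <- if (any(edge)) t[which(edge)[1]] else NA_real_

  tint <- sum(in_window & abs(final$x - config$planet_distance) <= config$planet_radius) /
    config$sample_rate

  out_of_start <- in_window & abs(final$x) > config$planet_radius
  rt <- if (any(out_of_start)) t[which(out_of_start)[1]] else NA_real_

  tibble::tibble(
    trial_index = log$trial_index,
    sr = sr,
    tr_ms = tr * 1000,
    tint_ms = tint * 1000,
    rt_ms = rt * 1000,
    rt_go_ms = (rt - hold) * 1000,
    success = log$success,
    resets = sum(log$events$event == "early_exit_reset")
  )
}

#' Per-trial metrics for a whole session
#'
#' @param session An `sg_session` from [run_session()].
#' @param config Optional [task_config()]; defaults to the one stored in the
#'   session.
#' @return A tibble with one row per trial, as in [trial_metrics()].
#' @export
session_metrics <- function(session, config = session$config) {
  purrr::map_dfr(session$trials, trial_metrics, config = config)
}

#' Session-mean Super G metrics
#'
#' Arithmetic means over the trials where each metric is defined; a metric
#' defined on zero trials yields an `NA` mean (propagated, not an error).
#' Average time in target and response time across the session are the
#' study's primary and secondary measures of individual performance.
#'
#' @param metrics A per-trial metrics tibble from [session_metrics()].
#' @return A one-row tibble: `mean_sr`, `mean_tr`, `mean_tint`, `mean_rt`,
#'   `mean_rt_go` (times in ms), `n_success`, per-metric defined-trial
#'   counts, and total resets.
#' @export
summarize_session <- function(metrics) {
  if (nrow(metrics) < 1) abort("metrics must contain at least one trial")
  mean_def <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  tibble::tibble(
    mean_sr = mean_def(metrics$sr),
    mean_tr = mean_def(metrics$tr_ms),
    mean_tint = mean(metrics$tint_ms),
    mean_rt = mean_def(metrics$rt_ms),
    mean_rt_go = mean_def(metrics$rt_go_ms),
    n_success = sum(metrics$success),
    n_sr = sum(!is.na(metrics$sr)),
    n_tr = sum(!is.na(metrics$tr_ms)),
    n_tint = nrow(metrics),
    n_rt = sum(!is.na(metrics$rt_ms)),
    n_resets = sum(metrics$resets)
  )
}
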