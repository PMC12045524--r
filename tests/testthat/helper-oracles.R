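# Independent oracles and fixture builders used across the suite.

# Naive full-scan metric extractor: an explicit sample-by-sample loop kept
# deliberately separate from the package's vectorized extractor.
oracle_trial_metrics <- function(log, config) {
  s <- as.data.frame(log$samples)
  s <- s[s$attempt == max(s$attempt), , drop = FALSE]
  hold <- config$hold_duration
  win_end <- hold + config$movement_window
  dt <- 1 / config$sample_rate
  n_left <- 0L
  n_right <- 0L
  n_in_target <- 0L
  rt <- NA_real_
  tr <- NA_real_
  for (i in seq_len(nrow(s))) {
    t <- s$t[i]
    if (t >= hold && t < win_end) {
      if (s$key_left[i]) n_left <- n_left + 1L
      if (s$key_right[i]) n_right <- n_right + 1L
      if (is.na(tr) && i > 1 && s$key_left[i] && !s$key_left[i - 1]) tr <- t
      if (is.na(rt) && abs(s$x[i]) > config$planet_radius) rt <- t
      if (abs(s$x[i] - config$planet_distance) <= config$planet_radius) {
        n_in_target <- n_in_target + 1L
      }
    }
  }
  list(
    sr = if (n_right > 0) n_left / n_right else NA_real_,
    tr_ms = tr * 1000,
    tint_ms = n_in_target / config$sample_rate * 1000,
    rt_ms = rt * 1000,
    rt_go_ms = (rt - hold) * 1000
  )
}

# a wide spread of plan policies, from near-ideal to erratic, to exercise
# every metric code path (lapses, no reversal, resets, early/late exits)
random_policy <- function() {
  make_policy(controller_params(
    t_go_mean = runif(1, 1.2, 2.6),
    tau_right = runif(1, 0.1, 1.1),
    rho = runif(1, 0.2, 2),
    t_rev_mean = runif(1, 1.6, 4.2),
    timing_sd = runif(1, 0, 0.35),
    lapse_prob = runif(1, 0, 0.3)
  ))
}

# hand-built trial log with explicit key intervals and a flat trajectory
flat_log <- function(config, right_on = numeric(), right_off = numeric(),
                     left_on = numeric(), left_off = numeric(),
                     x = NULL, success = FALSE) {
  n <- as.integer(round(config$trial_duration * config$sample_rate))
  t <- (0:n) / config$sample_rate
  in_int <- function(t, on, off) {
    out <- rep(FALSE, length(t))
    for (k in seq_along(on)) out <- out | (t >= on[k] & t < off[k])
    out
  }
  structure(
    list(
      trial_index = 0L,
      samples = tibble::tibble(
        attempt = 1L, t = t,
        x = if (is.null(x)) rep(0, n + 1) else x,
        v = rep(0, n + 1),
        key_left = in_int(t, left_on, left_off),
        key_right = in_int(t, right_on, right_off)
      ),
      events = tibble::tibble(attempt = 1L, time = config$hold_duration,
                              event = "go_cue"),
      success = success
    ),
    class = "sg_trial_log"
  )
}
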