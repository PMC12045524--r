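#' Advance the rate-control dynamics by one step
#'
#' The Super G cursor is a frictionless point mass on a 1-D axis: holding the
#' right arrow applies a constant positive acceleration, holding the left
#' arrow an equal negative one, and with no key (or both keys) held the
#' velocity is exactly conserved. Integration is semi-implicit Euler:
#' velocity is updated first, then position is advanced with the new
#' velocity.
#'
#' @param state A list with numeric fields `time`, `position`, `velocity`
#'   and logical `key_left`, `key_right` (the key state held over the step).
#' @param dt Step size in seconds (positive).
#' @param config A [task_config()].
#'
#' @return The state advanced by `dt` (keys unchanged).
#' @examples
#' s <- list(time = 0, position = 0, velocity = 0.5,
#'           key_left = FALSE, key_right = FALSE)
#' step_dynamics(s, 0.01, task_config())$position
#' @export
step_dynamics <- function(state, dt, config = task_config()) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    abort("dt must be a positive scalar")
  }
  if (!all(is.finite(c(state$time, state$position, state$velocity)))) {
    abort("invalid state: non-finite time, position or velocity")
  }
  if (!is.logical(state$key_left) || !is.logical(state$key_right) ||
      is.na(state$key_left) || is.na(state$key_right)) {
    abort("invalid state: key states must be TRUE/FALSE")
  }
  a <- config$force_accel * (as.numeric(state$key_right) - as.numeric(state$key_left))
  v <- state$velocity + a * dt
  state$velocity <- v
  state$position <- state$position + v * dt
  state$time <- state$time + dt
  state
}

# Vectorized semi-implicit Euler over the whole sample grid, matching the
# C++ fast path bitwise (cumsum accumulates in long double exactly as the
# C++ loop does).
integrate_keys <- function(key_left, key_right, cfg) {
  n <- length(key_left) - 1L
  dt <- 1 / cfg$sample_rate
  a <- cfg$force_accel * (as.numeric(key_right[-(n + 1L)]) -
                            as.numeric(key_left[-(n + 1L)]))
  a_dt <- a * dt
  v <- cumsum(a_dt)
  x <- cumsum(v * dt)
  list(v = c(0, v), x = c(0, x))
}

# ---- controllers -----------------------------------------------------------

#' Wrap a key-press function as a Super G controller
#'
#' The function is called once per attempt with the vector of sample times
#' (and, if it accepts a second argument, the 1-based attempt number) and
#' must return a data frame / list with logical elements `key_left` and
#' `key_right` of the same length. Anything non-logical violates the
#' controller contract and is an error.
#'
#' @param fn A function of `t` (and optionally `attempt`).
#' @return An object of class `sg_controller`.
#' @examples
#' # a controller that never presses anything
#' idle <- as_controller(function(t) {
#'   list(key_left = rep(FALSE, length(t)), key_right = rep(FALSE, length(t)))
#' })
#' @export
as_controller <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(kind = "fn", fn = fn, stateful = length(formals(fn)) >= 2),
            class = "sg_controller")
}

#' @rdname as_controller
#' @export
null_controller <- function() {
  as_controller(function(t) {
    list(key_left = rep(FALSE, length(t)), key_right = rep(FALSE, length(t)))
  })
}

#' Ideal bang-bang controller
#'
#' The time-optimal open-loop strategy for the default task: exit exactly at
#' the go cue, thrust right for `tau = sqrt(planet_distance / force_accel)`
#' seconds, then brake left for the same duration, arriving at the target
#' center at rest. Under the default geometry this lands every trial with
#' comfortable margin and serves as the feasibility benchmark.
#'
#' @param config A [task_config()].
#' @return An `sg_policy` with zero timing noise and zero lapse rate.
#' @export
bang_bang_controller <- function(config = task_config()) {
  tau <- sqrt(config$planet_distance / config$force_accel)
  make_policy(controller_params(
    t_go_mean = config$hold_duration,
    tau_right = tau,
    rho = 1,
    t_rev_mean = config$hold_duration + tau,
    timing_sd = 0,
    lapse_prob = 0
  ))
}

# realize one attempt plan from controller params; consumes the RNG stream
# in the fixed order (lapse uniform, then normals t_go, tau_r, tau_l, t_rev)
# shared with the C++ fast path
draw_plan <- function(p) {
  if (runif(1) < p$lapse_prob) {
    return(list(lapse = TRUE, t_go = 0, tau_r = 0, tau_l = 0, t_rev = 0))
  }
  sd <- p$timing_sd
  t_go <- p$t_go_mean + rnorm(1) * sd
  tau_r <- max(0, p$tau_right + rnorm(1) * sd)
  tau_l <- max(0, p$rho * tau_r + rnorm(1) * sd)
  t_rev <- max(t_go + tau_r, p$t_rev_mean + rnorm(1) * sd)
  list(lapse = FALSE, t_go = t_go, tau_r = tau_r, tau_l = tau_l, t_rev = t_rev)
}

plan_keys <- function(plan, t) {
  if (plan$lapse) {
    return(list(key_left = rep(FALSE, length(t)), key_right = rep(FALSE, length(t))))
  }
  list(
    key_left = t >= plan$t_rev & t < plan$t_rev + plan$tau_l,
    key_right = t >= plan$t_go & t < plan$t_go + plan$tau_r
  )
}

controller_keys <- function(controller, t, attempt) {
  if (inherits(controller, "sg_policy")) {
    keys <- plan_keys(draw_plan(controller$params), t)
  } else if (inherits(controller, "sg_controller")) {
    keys <- if (controller$stateful) controller$fn(t, attempt) else controller$fn(t)
  } else {
    abort("controller must be an sg_policy or sg_controller")
  }
  kl <- keys$key_left
  kr <- keys$key_right
  if (!is.logical(kl) || !is.logical(kr) ||
      length(kl) != length(t) || length(kr) != length(t) ||
      anyNA(kl) || anyNA(kr)) {
    abort(paste("controller contract violated: key states must be logical",
                "vectors matching the sample grid, without NA"))
  }
  list(key_left = kl, key_right = kr)
}

# ---- trial and session -----------------------------------------------------

#' Run one Super G trial
#'
#' Simulates the full trial state machine at the task's sample rate. During
#' the hold phase the cursor must stay within the start planet's radius;
#' leaving earlier fires an `early_exit_reset` event, resets position,
#' velocity and the trial clock, and restarts the attempt without consuming
#' one of the session's 75 attempts. After the go cue the trial succeeds at
#' the first instant the cursor has stayed within the target planet's radius
#' for `landing_duration` continuously (a `landed` event; remaining samples
#' are not emitted). A movement window elapsing without landing is a failed
#' trial.
#'
#' @param config A [task_config()].
#' @param controller An [as_controller()] function controller or a
#'   [make_policy()] plan policy.
#' @param trial_index 0-based index recorded in the log.
#' @param seed Optional integer seed; when `NULL` the ambient RNG stream is
#'   used (so sessions draw one continuous stream).
#'
#' @return An object of class `sg_trial_log`: a list with `trial_index`,
#'   `samples` (tibble: `attempt`, `t`, `x`, `v`, `key_left`, `key_right`),
#'   `events` (tibble: `attempt`, `time`, `event`) and `success`.
#' @examples
#' log <- run_trial(task_config(), bang_bang_controller())
#' log$success
#' @export
run_trial <- function(config, controller, trial_index = 0L, seed = NULL) {
  validate_task_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- n_steps(config)
  dt <- 1 / config$sample_rate
  t <- (0:n) * dt
  hold <- config$hold_duration
  radius <- config$planet_radius

  samples <- vector("list", config$max_resets + 1L)
  events <- list()
  attempt <- 1L
  repeat {
    keys <- controller_keys(controller, t, attempt)
    traj <- integrate_keys(keys$key_left, keys$key_right, config)
    reset_at <- which(t < hold & abs(traj$x) > radius)[1]

    if (!is.na(reset_at)) {
      idx <- seq_len(reset_at)
      samples[[attempt]] <- tibble::tibble(
        attempt = attempt, t = t[idx], x = traj$x[idx], v = traj$v[idx],
        key_left = keys$key_left[idx], key_right = keys$key_right[idx]
      )
      events[[length(events) + 1L]] <-
        tibble::tibble(attempt = attempt, time = t[reset_at],
                       event = "early_exit_reset")
      if (attempt >= config$max_resets) {
        # abandoned: repeated early exits, trial counts as failed
        events[[length(events) + 1L]] <-
          tibble::tibble(attempt = attempt, time = t[reset_at],
                         event = "trial_end")
        success <- FALSE
        break
      }
      attempt <- attempt + 1L
      next
    }

    in_window <- t >= hold & t < hold + config$movement_window
    in_target <- in_window & abs(traj$x - config$planet_distance) <= radius
    land_samples <- as.integer(round(config$landing_duration * config$sample_rate))
    runs <- rle(in_target)
    run_ends <- cumsum(runs$lengths)
    hit <- which(runs$values & runs$lengths >= land_samples)[1]
    events[[length(events) + 1L]] <-
      tibble::tibble(attempt = attempt, time = hold, event = "go_cue")
    if (!is.na(hit)) {
      start <- run_ends[hit] - runs$lengths[hit] + 1L
      end <- start + land_samples - 1L
      success <- TRUE
      events[[length(events) + 1L]] <-
        tibble::tibble(attempt = attempt, time = t[end],
                       event = c("landed", "trial_end"))
    } else {
      end <- n + 1L
      success <- FALSE
      events[[length(events) + 1L]] <-
        tibble::tibble(attempt = attempt, time = t[end], event = "trial_end")
    }
    idx <- seq_len(end)
    samples[[attempt]] <- tibble::tibble(
      attempt = attempt, t = t[idx], x = traj$x[idx], v = traj$v[idx],
      key_left = keys$key_left[idx], key_right = keys$key_right[idx]
    )
    break
  }

  structure(
    list(
      trial_index = as.integer(trial_index),
      samples = dplyr::bind_rows(samples[!vapply(samples, is.null, logical(1))]),
      events = dplyr::bind_rows(events),
      success = success
    ),
    class = "sg_trial_log"
  )
}

#' @export
print.sg_trial_log <- function(x, ...) {
  cat(sprintf("<Super G trial %d: %s, %d attempt(s), %d samples>\n",
              x$trial_index, if (x$success) "landed" else "failed",
              max(x$samples$attempt), nrow(x$samples)))
  invisible(x)
}

#' Run a full Super G session
#'
#' Runs `n_trials` trials with the given controller and threads the planet
#' chain through them: after a success the previous target becomes the next
#' start planet and a new target appears; after a failure the pair is
#' unchanged.
#'
#' @inheritParams run_trial
#' @param hour_played Hour of day on the 24-hour clock recorded with the
#'   session (used downstream as a covariate); `NA` unless supplied or
#'   derivable from `timestamp`.
#' @param timestamp Optional POSIXct recorded verbatim in the log.
#'
#' @return An object of class `sg_session`: `trials` (list of
#'   [run_trial()] logs), `planets` (tibble with `trial`, `start_planet`,
#'   `target_planet`, `success`), `hour_played`, `timestamp`, `config`.
#' @examples
#' sess <- run_session(task_config(n_trials = 3), bang_bang_controller(), seed = 1)
#' sess$planets
#' @export
run_session <- function(config, controller, seed = NULL,
                        hour_played = NA_integer_, timestamp = NULL) {
  validate_task_config(config)
  if (!is.null(seed)) set.seed(seed)
  if (is.na(hour_played) && !is.null(timestamp)) {
    hour_played <- as.integer(format(timestamp, "%H"))
  }
  trials <- vector("list", config$n_trials)
  start <- 1L
  target <- 2L
  planets <- matrix(0L, nrow = config$n_trials, ncol = 2)
  success <- logical(config$n_trials)
  for (i in seq_len(config$n_trials)) {
    trials[[i]] <- run_trial(config, controller, trial_index = i - 1L)
    planets[i, ] <- c(start, target)
    success[i] <- trials[[i]]$success
    if (success[i]) {
      start <- target
      target <- (target %% config$n_planets) + 1L
    }
  }
  structure(
    list(
      trials = trials,
      planets = tibble::tibble(
        trial = seq_len(config$n_trials) - 1L,
        start_planet = planets[, 1], target_planet = planets[, 2],
        success = success
      ),
      hour_played = hour_played,
      timestamp = timestamp,
      config = config
    ),
    class = "sg_session"
  )
}

#' @export
print.sg_session <- function(x, ...) {
  cat(sprintf("<Super G session: %d trials, %d landed, hour %s>\n",
              length(x$trials), sum(x$planets$success),
              ifelse(is.na(x$hour_played), "?", x$hour_played)))
  invisible(x)
}
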