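#' Task geometry and timing for the Super G trial state machine
#'
#' Bundles every constant the simulator needs: the 1.5 s hold phase during
#' which the astronaut may not leave the start planet, the 3 s movement
#' window, the 1 s continuous-landing requirement, the 100 Hz sample grid,
#' and the (configurable) 1-D geometry and thrust. Defaults reproduce the
#' published task timing; the geometry and thrust are not published, so the
#' defaults are chosen such that the ideal bang-bang strategy completes each
#' trial with at least half a second to spare (see the methods vignette).
#'
#' @param hold_duration Seconds before the go cue; leaving the start planet
#'   earlier resets the trial.
#' @param movement_window Seconds available to land after the go cue.
#' @param trial_duration Total trial length in seconds; must equal
#'   `hold_duration + movement_window`.
#' @param landing_duration Seconds the cursor must stay continuously inside
#'   the target planet to land.
#' @param sample_rate Sampling and integration rate in Hz.
#' @param force_accel Acceleration applied while exactly one arrow key is
#'   held, in screen-units/s^2.
#' @param planet_distance Distance between start and target planet centers,
#'   in screen-units.
#' @param planet_radius Planet radius in screen-units; the boundary test is
#'   point-in-disk with ties counting as inside.
#' @param n_trials Attempts per session.
#' @param n_planets Planets in the chain; the target id advances on success.
#' @param max_resets Early-exit resets tolerated per trial before the trial
#'   is abandoned as failed (guards against controllers that always exit
#'   during the hold phase).
#'
#' @return A list of class `sg_task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$trial_duration
#' @export
task_config <- function(hold_duration = 1.5,
                        movement_window = 3.0,
                        trial_duration = hold_duration + movement_window,
                        landing_duration = 1.0,
                        sample_rate = 100,
                        force_accel = 2.0,
                        planet_distance = 1.0,
                        planet_radius = 0.08,
                        n_trials = 75,
                        n_planets = 16,
                        max_resets = 20) {
  cfg <- list(
    hold_duration = hold_duration,
    movement_window = movement_window,
    trial_duration = trial_duration,
    landing_duration = landing_duration,
    sample_rate = sample_rate,
    force_accel = force_accel,
    planet_distance = planet_distance,
    planet_radius = planet_radius,
    n_trials = as.integer(n_trials),
    n_planets = as.integer(n_planets),
    max_resets = as.integer(max_resets)
  )
  validate_task_config(cfg)
  structure(cfg, class = "sg_task_config")
}

validate_task_config <- function(cfg) {
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) abort("all task config fields must be numeric")
  if (!all(vapply(cfg, function(x) is.finite(x) && length(x) == 1, logical(1)))) {
    abort("all task config fields must be finite scalars")
  }
  if (cfg$hold_duration <= 0 || cfg$movement_window <= 0) {
    abort("hold_duration and movement_window must be positive")
  }
  if (abs(cfg$trial_duration - (cfg$hold_duration + cfg$movement_window)) > 1e-9) {
    abort("trial_duration must equal hold_duration + movement_window")
  }
  if (cfg$landing_duration > cfg$movement_window) {
    abort("landing_duration must not exceed movement_window")
  }
  if (cfg$planet_radius >= cfg$planet_distance / 2) {
    abort("planet_radius must be smaller than planet_distance / 2")
  }
  if (cfg$sample_rate <= 0) abort("sample_rate must be positive")
  if (cfg$n_trials < 1 || cfg$n_planets < 1) {
    abort("n_trials and n_planets must be at least 1")
  }
  invisible(cfg)
}

#' @export
print.sg_task_config <- function(x, ...) {
  cat("<Super G task config>\n")
  cat(sprintf("  trial: %.2f s = %.2f s hold + %.2f s movement window\n",
              x$trial_duration, x$hold_duration, x$movement_window))
  cat(sprintf("  landing: %.2f s continuous inside radius %.3f at distance %.2f\n",
              x$landing_duration, x$planet_radius, x$planet_distance))
  cat(sprintf("  %d trials, %d planets, %g Hz sampling, thrust %.2f u/s^2\n",
              x$n_trials, x$n_planets, x$sample_rate, x$force_accel))
  invisible(x)
}

# number of integration steps per attempt (samples 0..n_steps)
n_steps <- function(cfg) as.integer(round(cfg$trial_duration * cfg$sample_rate))
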