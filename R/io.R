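SG_SCHEMA_VERSION <- 1L

#' Write / read a session log as JSON lines
#'
#' `write_session()` stores the 100 Hz samples one JSON object per line
#' (`trial`, `attempt`, `t`, `x`, `v`, `kL`, `kR`) in the main file, with a
#' sidecar (`<path>.meta.jsonl`) holding the schema version, task config,
#' hour played, planet chain, per-trial outcomes and the event stream.
#' `read_session()` reconstructs the full `sg_session`; the round trip is
#' lossless up to floating-point text representation. A truncated or
#' corrupted file raises a malformed-log error rather than returning a
#' partial session.
#'
#' @param session An `sg_session` from [run_session()].
#' @param path Path of the samples file; the sidecar is `<path>.meta.jsonl`.
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns an `sg_session`.
#' @export
write_session <- function(session, path) {
  samples <- purrr::map_dfr(session$trials, function(tr) {
    s <- tr$samples
    tibble::tibble(trial = tr$trial_index, attempt = s$attempt, t = s$t,
                   x = s$x, v = s$v, kL = s$key_left, kR = s$key_right)
  })
  con <- file(path, open = "w")
  on.exit(close(con), add = TRUE)
  jsonlite::stream_out(samples, con, verbose = FALSE, digits = NA)

  meta_path <- paste0(path, ".meta.jsonl")
  meta <- jsonlite::toJSON(
    list(type = "meta", schema = SG_SCHEMA_VERSION,
         n_trials = length(session$trials),
         hour_played = session$hour_played,
         timestamp = if (is.null(session$timestamp)) NULL else
           format(session$timestamp, "%Y-%m-%dT%H:%M:%S"),
         config = unclass(session$config)),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  trials <- purrr::map2_chr(session$trials, seq_along(session$trials), function(tr, i) {
    jsonlite::toJSON(
      list(type = "trial", trial = tr$trial_index, success = tr$success,
           start_planet = session$planets$start_planet[i],
           target_planet = session$planets$target_planet[i]),
      auto_unbox = TRUE
    )
  })
  events <- unlist(purrr::map(session$trials, function(tr) {
    purrr::pmap_chr(tr$events, function(attempt, time, event) {
      jsonlite::toJSON(
        list(type = "event", trial = tr$trial_index, attempt = attempt,
             time = time, event = event),
        auto_unbox = TRUE, digits = NA
      )
    })
  }))
  writeLines(c(meta, trials, events), meta_path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  meta_path <- paste0(path, ".meta.jsonl")
  if (!file.exists(path) || !file.exists(meta_path)) {
    abort("session files not found (need both the samples file and its .meta.jsonl sidecar)")
  }
  parse_line <- function(line) {
    tryCatch(jsonlite::fromJSON(line), error = function(e) {
      abort("malformed log: invalid JSON line in session file")
    })
  }
  meta_lines <- readLines(meta_path, warn = FALSE)
  if (!length(meta_lines)) abort("malformed log: empty sidecar")
  records <- lapply(meta_lines, parse_line)
  meta <- records[[1]]
  if (is.null(meta$type) || meta$type != "meta") {
    abort("malformed log: sidecar must start with a meta record")
  }
  if (meta$schema != SG_SCHEMA_VERSION) {
    abort(sprintf("schema version mismatch: file has %s, reader supports %d",
                  meta$schema, SG_SCHEMA_VERSION))
  }
  config <- do.call(task_config, meta$config[setdiff(names(meta$config), character())])

  samples <- tryCatch(
    jsonlite::stream_in(file(path), verbose = FALSE),
    error = function(e) abort("malformed log: could not parse samples JSONL")
  )
  need <- c("trial", "attempt", "t", "x", "v", "kL", "kR")
  if (!all(need %in% names(samples))) {
    abort("malformed log: samples file lacks required fields")
  }

  trial_recs <- records[vapply(records, function(r) identical(r$type, "trial"), logical(1))]
  event_recs <- records[vapply(records, function(r) identical(r$type, "event"), logical(1))]
  if (length(trial_recs) != meta$n_trials) {
    abort("malformed log: trial record count does not match meta")
  }

  trials <- lapply(trial_recs, function(tr) {
    s <- samples[samples$trial == tr$trial, , drop = FALSE]
    if (!nrow(s)) abort("malformed log: trial has no samples")
    ev <- purrr::map_dfr(
      event_recs[vapply(event_recs, function(e) e$trial == tr$trial, logical(1))],
      function(e) tibble::tibble(attempt = as.integer(e$attempt),
                                 time = e$time, event = e$event)
    )
    structure(
      list(
        trial_index = as.integer(tr$trial),
        samples = tibble::tibble(
          attempt = as.integer(s$attempt), t = s$t, x = s$x, v = s$v,
          key_left = as.logical(s$kL), key_right = as.logical(s$kR)
        ),
        events = ev,
        success = as.logical(tr$success)
      ),
      class = "sg_trial_log"
    )
  })
  planets <- purrr::map_dfr(trial_recs, function(tr) {
    tibble::tibble(trial = as.integer(tr$trial),
                   start_planet = as.integer(tr$start_planet),
                   target_planet = as.integer(tr$target_planet),
                   success = as.logical(tr$success))
  })
  structure(
    list(
      trials = trials,
      planets = planets,
      hour_played = if (is.null(meta$hour_played)) NA_integer_ else
        as.integer(meta$hour_played),
      timestamp = if (is.null(meta$timestamp)) NULL else
        as.POSIXct(meta$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = ""),
      config = config
    ),
    class = "sg_session"
  )
}

#' Flat CSV export of a session's samples
#'
#' A documented-lossy export (events are not included; recover them from
#' the JSONL representation) for use in other stats environments.
#'
#' @param session An `sg_session`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
session_to_csv <- function(session, path) {
  samples <- purrr::map_dfr(session$trials, function(tr) {
    s <- tr$samples
    tibble::tibble(trial = tr$trial_index, attempt = s$attempt, t = s$t,
                   x = s$x, v = s$v, kL = s$key_left, kR = s$key_right,
                   success = tr$success)
  })
  readr::write_csv(samples, path)
  invisible(path)
}

#' Run the full study pipeline under one seed
#'
#' Cohort generation, gameplay simulation, preprocessing and the chosen
#' regression models, end to end, with a manifest recording the seed,
#' configuration hash and stage counts. Two runs with the same inputs and
#' seed produce identical results.
#'
#' @param cohort A [cohort_config()].
#' @param link A [covariate_link()].
#' @param task A [task_config()].
#' @param models Integer vector of model ids to fit (possibly empty).
#' @param seed Integer seed for the whole run.
#' @param ci_method Passed to [fit_model()].
#' @return An object of class `sg_pipeline`: `cohort`, `analysis`,
#'   `standardized`, `fits` (named list, empty if no models requested) and
#'   `manifest`.
#' @examples
#' \donttest{
#' res <- run_pipeline(cohort_config(n = 60), seed = 42, models = 3,
#'                     ci_method = "wald")
#' res$manifest$n_carriers
#' }
#' @export
run_pipeline <- function(cohort = cohort_config(), link = covariate_link(),
                         task = task_config(), models = 1:5, seed = 1,
                         ci_method = "profile") {
  set.seed(seed)
  cohort_tbl <- generate_cohort(cohort)
  analysis <- simulate_study(cohort_tbl, link = link, task = task)
  standardized <- standardize_analysis(analysis)
  fits <- if (length(models)) {
    fit_study_models(standardized, models = models, ci_method = ci_method)
  } else {
    list()
  }
  carrier <- carrier_status(cohort_tbl$apoe_genotype)
  manifest <- list(
    seed = seed,
    schema = SG_SCHEMA_VERSION,
    config_hash = rlang::hash(list(cohort, link, task, models)),
    n_participants = nrow(cohort_tbl),
    n_trials_per_session = task$n_trials,
    n_carriers = sum(carrier),
    n_noncarriers = sum(!carrier),
    n_female = sum(cohort_tbl$sex == "female"),
    n_male = sum(cohort_tbl$sex == "male"),
    models_fit = if (length(fits)) names(fits) else character()
  )
  structure(
    list(cohort = cohort_tbl, analysis = analysis, standardized = standardized,
         fits = fits, manifest = manifest),
    class = "sg_pipeline"
  )
}

#' @export
print.sg_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("<Super G study pipeline>\n")
  cat(sprintf("  seed %d, config %s\n", m$seed, substr(m$config_hash, 1, 8)))
  cat(sprintf("  %d participants: %d APOE e4 carriers / %d noncarriers, %d female / %d male\n",
              m$n_participants, m$n_carriers, m$n_noncarriers,
              m$n_female, m$n_male))
  cat(sprintf("  mean time in target %.1f ms, mean response time %.1f ms\n",
              mean(x$analysis$mean_tint), mean(x$analysis$mean_rt, na.rm = TRUE)))
  if (length(x$fits)) {
    cat("  models fit:", paste(names(x$fits), collapse = ", "), "\n")
  }
  invisible(x)
}
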