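#' Read and write gait trials as delimited tables
#'
#' The on-disk trial format is a plain CSV with one row per sample and the
#' fixed header `time, angle_rad, grf_v_N, semg_lgs, semg_sol, mt_lgs_mm,
#' mt_sol_mm, moment_Nm` (`moment_Nm` optional). Unknown extra columns are
#' ignored with a warning; a missing mandatory column is a schema error
#' naming the column. Trial metadata (speed, body mass, processing flags)
#' travels in a sidecar of `#`-prefixed header comments written by
#' [write_gait_trial()].
#'
#' @param path file path.
#' @param speed,body_mass trial metadata; when reading, values in the file
#'   header take precedence and these act as fallbacks.
#' @param semg_is_envelope,mt_is_filtered processing flags, see
#'   [gait_trial()].
#' @return `read_gait_trial()` returns a [gait_trial]; `write_gait_trial()`
#'   returns `path` invisibly.
#' @export
read_gait_trial <- function(path, speed = NA, body_mass = NA,
                            semg_is_envelope = FALSE, mt_is_filtered = FALSE) {
  hdr <- readLines(path, n = 20)
  meta <- list()
  for (ln in grep("^#", hdr, value = TRUE)) {
    kv <- sub("^#\\s*", "", ln)
    parts <- strsplit(kv, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2)
      meta[[trimws(parts[1])]] <- trimws(parts[2])
  }
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("time", "angle_rad", "grf_v_N", "semg_lgs", "semg_sol",
            "mt_lgs_mm", "mt_sol_mm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(d), c(need, "moment_Nm"))
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  fs <- 1 / stats::median(diff(d$time))
  fs <- round(fs, 6)
  num <- function(key, fallback) {
    v <- meta[[key]]
    if (is.null(v)) fallback else as.numeric(v)
  }
  flag <- function(key, fallback)
    if (is.null(meta[[key]])) fallback else identical(meta[[key]], "TRUE")
  mk <- function(col, units) uniform_series(d[[col]], fs = fs, t0 = d$time[1],
                                            units = units)
  channels <- list(angle = mk("angle_rad", "rad"), grf = mk("grf_v_N", "N"),
                   semg_lgs = mk("semg_lgs", ""), semg_sol = mk("semg_sol", ""),
                   mt_lgs = mk("mt_lgs_mm", "mm"),
                   mt_sol = mk("mt_sol_mm", "mm"))
  if ("moment_Nm" %in% names(d)) channels$moment <- mk("moment_Nm", "N.m")
  gait_trial(channels,
             speed = num("speed_mps", speed),
             body_mass = num("body_mass_kg", body_mass),
             semg_is_envelope = flag("semg_is_envelope", semg_is_envelope),
             mt_is_filtered = flag("mt_is_filtered", mt_is_filtered),
             id = if (!is.null(meta$id)) meta$id
             else tools::file_path_sans_ext(basename(path)))
}

#' @rdname read_gait_trial
#' @param trial a [gait_trial] object.
#' @export
write_gait_trial <- function(trial, path) {
  ch <- trial$channels
  n <- length(ch$angle$values)
  d <- data.frame(time = series_time(ch$angle),
                  angle_rad = ch$angle$values, grf_v_N = ch$grf$values,
                  semg_lgs = ch$semg_lgs$values, semg_sol = ch$semg_sol$values,
                  mt_lgs_mm = ch$mt_lgs$values, mt_sol_mm = ch$mt_sol$values)
  if (!is.null(ch$moment)) d$moment_Nm <- ch$moment$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s",
                     c("id", "speed_mps", "body_mass_kg", "semg_is_envelope",
                       "mt_is_filtered"),
                     c(trial$id, format(trial$speed, digits = 15),
                       format(trial$body_mass, digits = 15),
                       trial$semg_is_envelope, trial$mt_is_filtered)), con)
  fmt <- vapply(d, function(col) formatC(col, digits = 15, format = "g"),
                character(n))
  writeLines(paste(colnames(d), collapse = ","), con)
  writeLines(apply(fmt, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Write and read calibration results as JSON
#'
#' Serializes the calibrated parameter set with its bounds, objective value,
#' convergence flag, variant, mode and seed (schema-versioned), so a fit can
#' be archived next to its outputs and reloaded.
#'
#' @param fit an [hnm_fit] object.
#' @param path file path (`.json`).
#' @return `write_hnm_result()` returns `path` invisibly;
#'   `read_hnm_result()` returns the parsed result list with `params` as an
#'   [hnm_parameters()] object.
#' @export
write_hnm_result <- function(fit, path) {
  res <- list(schema = "hillfuse-result/1",
              variant = fit$variant, mode = fit$mode,
              speed = fit$speed, seed = fit$seed,
              params = list(lgs = fit$params$lgs, sol = fit$params$sol),
              bounds = fit$bounds, objective = fit$objective,
              start_objective = fit$start_objective,
              n_evals = fit$n_evals, converged = fit$converged)
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_hnm_result
#' @export
read_hnm_result <- function(path) {
  res <- jsonlite::read_json(path, simplifyVector = TRUE)
  res$params <- hnm_parameters(lgs = as.list(res$params$lgs),
                               sol = as.list(res$params$sol))
  res
}

#' Write a metrics table as tidy CSV
#'
#' One row per cycle/variant/mode/speed cell; an empty table yields a
#' header-only file.
#'
#' @param metrics a data frame of metric results.
#' @param path file path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Reads filter, activation, optimizer and synthetic-generator settings from
#' a YAML file and materializes them as package objects; unknown top-level
#' keys are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return A list with entries `control` ([hnm_control()]), `constants`
#'   and `synthetic` ([synthetic_config()]), each present when configured.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("control", "constants", "synthetic")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("config error: unknown top-level key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- list()
  if (!is.null(cfg$control)) {
    act <- cfg$control$activation
    args <- cfg$control[setdiff(names(cfg$control), "activation")]
    if (!is.null(act))
      args$activation <- do.call(activation_filter_params, act)
    out$control <- do.call(hnm_control, args)
  } else out$control <- hnm_control()
  out$constants <- if (!is.null(cfg$constants))
    lapply(cfg$constants, function(x) do.call(muscle_constants, x))
  else default_muscle_constants()
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    if (!is.null(syn$true_params))
      syn$true_params <- do.call(hnm_parameters, syn$true_params)
    out$synthetic <- do.call(synthetic_config, syn)
  }
  out
}
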