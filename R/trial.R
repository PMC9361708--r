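#' Gait trial container
#'
#' One subject-by-speed walking trial: a bundle of time-synchronized channels
#' plus body mass and metadata. Channels are [uniform_series]: `angle`
#' (anatomical ankle angle, rad, dorsiflexion positive), `grf` (vertical
#' ground reaction force, N), `semg_lgs`/`semg_sol` (sEMG, raw or envelope),
#' `mt_lgs`/`mt_sol` (muscle thickness, mm) and optionally `moment` (benchmark
#' net plantarflexion moment from inverse dynamics, N m).
#'
#' @param channels named list of [uniform_series] with the channel names
#'   above (`moment` optional).
#' @param speed treadmill speed in m/s.
#' @param body_mass subject body mass in kg.
#' @param semg_is_envelope logical: `TRUE` if the sEMG channels already hold
#'   the linear envelope (no band-pass/rectification needed).
#' @param mt_is_filtered logical: `TRUE` if the thickness channels are already
#'   low-pass filtered.
#' @param id trial identifier.
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(channels, speed, body_mass,
                       semg_is_envelope = FALSE, mt_is_filtered = FALSE,
                       id = sprintf("trial_%gms", speed)) {
  need <- c("angle", "grf", "semg_lgs", "semg_sol", "mt_lgs", "mt_sol")
  miss <- setdiff(need, names(channels))
  if (length(miss))
    stop("schema error: missing channel(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (body_mass <= 0) stop("config error: body_mass must be positive",
                           call. = FALSE)
  structure(list(channels = channels, speed = speed, body_mass = body_mass,
                 semg_is_envelope = semg_is_envelope,
                 mt_is_filtered = mt_is_filtered, id = id, proc = NULL),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %s: %.2f m/s, %.1f kg, %d channels\n",
              x$id, x$speed, x$body_mass, length(x$channels)))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-9s %6d samples @ %g Hz\n", nm, length(ch$values), ch$fs))
  }
  if (!is.null(x$proc))
    cat(sprintf("  processed: %d stance cycles on the %g Hz model grid\n",
                nrow(x$proc$stance), x$proc$fs))
  invisible(x)
}

#' Preprocess trials into model inputs
#'
#' Turns raw trial channels into the model inputs on a common grid: sEMG is
#' enveloped (unless already an envelope), all channels are resampled to the
#' model rate, envelopes are normalized to the subject's cross-speed task
#' peak, muscle thickness is low-pass filtered (unless already filtered) and
#' normalized to the subject-constant bounds, the neural-activation filter is
#' applied (its output depends only on fixed settings, not on calibrated
#' parameters, so it is precomputed here), and stance cycles are segmented
#' from the vertical GRF.
#'
#' @param trials list of [gait_trial] objects from one subject.
#' @param constants per-muscle constants, as [default_muscle_constants()].
#' @param control an [hnm_control()] list.
#' @return The trial list with a `proc` element added to each trial: model-grid
#'   vectors `theta`, `grf`, `u_lgs`, `u_sol`, `N_lgs`, `N_sol`, `a2_lgs`,
#'   `a2_sol`, `moment`, the stance table, and `fs`. The task peaks used are
#'   attached as an attribute `task_peaks`.
#' @export
prepare_trials <- function(trials, constants = default_muscle_constants(),
                           control = hnm_control()) {
  stopifnot(length(trials) >= 1)
  fs <- control$fs_model

  env <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    e <- list()
    for (m in c("lgs", "sol")) {
      ch <- tr$channels[[paste0("semg_", m)]]
      x <- if (tr$semg_is_envelope) ch
      else bandpass_envelope(ch, band_lo = control$semg_band[1],
                             band_hi = control$semg_band[2],
                             env_cutoff = control$env_cutoff,
                             order = control$filter_order)
      x <- resample_series(x, fs)
      e[[m]] <- pmax(.series_values(x), 0)
    }
    env[[i]] <- e
  }
  task_peak <- c(lgs = max(vapply(env, function(e) max(e$lgs), 1)),
                 sol = max(vapply(env, function(e) max(e$sol), 1)))
  if (any(task_peak <= 0))
    stop("config error: task peak is not positive; check sEMG channels",
         call. = FALSE)

  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    theta <- .series_values(resample_series(tr$channels$angle, fs))
    grf <- .series_values(resample_series(tr$channels$grf, fs))
    n <- min(length(theta), length(grf))

    u <- lapply(c(lgs = "lgs", sol = "sol"), function(m)
      normalize_envelope(env[[i]][[m]], task_peak[[m]]))
    N <- lapply(u, function(x)
      .series_values(neural_activation(x, control$activation, fs = fs)))

    a2 <- lapply(c(lgs = "lgs", sol = "sol"), function(m) {
      ch <- resample_series(tr$channels[[paste0("mt_", m)]], fs)
      if (!tr$mt_is_filtered)
        ch <- filter_mt(ch, cutoff = control$mt_cutoff,
                        order = control$filter_order)
      .series_values(us_activation(ch, constants[[m]]$mt_min,
                                   constants[[m]]$mt_max))
    })

    moment <- if (!is.null(tr$channels$moment))
      .series_values(resample_series(tr$channels$moment, fs)) else NULL

    clip <- function(x) x[seq_len(min(n, length(x)))]
    stance <- segment_stance(clip(grf), fs = fs,
                             threshold = control$stance_threshold,
                             min_duration = control$min_stance)
    trials[[i]]$proc <- list(
      fs = fs, theta = clip(theta), grf = clip(grf),
      u_lgs = clip(u$lgs), u_sol = clip(u$sol),
      N_lgs = clip(N$lgs), N_sol = clip(N$sol),
      a2_lgs = clip(a2$lgs), a2_sol = clip(a2$sol),
      moment = if (is.null(moment)) NULL else clip(moment),
      stance = stance)
  }
  attr(trials, "task_peaks") <- task_peak
  class(trials) <- "gait_trials"
  trials
}

#' @export
print.gait_trials <- function(x, ...) {
  cat(sprintf("<gait_trials> %d trial(s)\n", length(x)))
  for (tr in x) print(tr)
  invisible(x)
}
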