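#' Assemble a calibration dataset from processed trials
#'
#' Selects stance cycles for calibration and held-out prediction. "Steady"
#' cycles are those whose duration lies within a tolerance (default 10\%) of
#' the trial median. Single-speed mode draws 10 steady cycles from the trial
#' at the requested speed; inter-speed mode draws 2 steady cycles from each of
#' the five speeds. Held-out cycles (up to `n_holdout` per trial) are steady
#' cycles disjoint from the calibration set. Selection is deterministic given
#' the seed.
#'
#' @param trials processed trials from [prepare_trials()] (must carry the
#'   benchmark moment channel).
#' @param mode `"inter"` or `"single"`.
#' @param speed calibration speed in m/s (required for single-speed mode).
#' @param n_calib total calibration cycles (default 10).
#' @param n_holdout held-out cycles per trial (default 5).
#' @param seed integer seed for the cycle draw.
#' @param control an [hnm_control()] list (steadiness tolerance).
#' @return A list of class `hnm_dataset`: `calib` and `holdout` are data
#'   frames with columns `trial`, `speed`, `heel_strike_idx`, `toe_off_idx`;
#'   `trials` holds the processed trials; `mode`, `speed`, `seed` record
#'   provenance.
#' @export
build_calibration_dataset <- function(trials, mode = c("inter", "single"),
                                      speed = NULL, n_calib = 10,
                                      n_holdout = 5, seed = 1,
                                      control = hnm_control()) {
  mode <- match.arg(mode)
  if (is.null(attr(trials, "task_peaks")))
    stop("data error: run prepare_trials() first", call. = FALSE)
  for (tr in trials)
    if (is.null(tr$proc$moment))
      stop("data error: benchmark moment channel required for calibration",
           call. = FALSE)

  steady <- lapply(trials, function(tr) {
    st <- tr$proc$stance
    med <- stats::median(st$duration_s)
    st[abs(st$duration_s - med) <= control$steady_tol * med, , drop = FALSE]
  })

  pick <- function(j, k, avoid = integer(0)) {
    st <- steady[[j]]
    avail <- setdiff(seq_len(nrow(st)), avoid)
    if (length(avail) < k)
      stop("data error: trial ", trials[[j]]$id, " has only ", length(avail),
           " steady cycles available, need ", k, call. = FALSE)
    sort(sample(avail, k))
  }
  as_block <- function(j, rows) {
    st <- steady[[j]][rows, , drop = FALSE]
    data.frame(trial = j, speed = trials[[j]]$speed,
               heel_strike_idx = st$heel_strike_idx,
               toe_off_idx = st$toe_off_idx)
  }

  .with_seed(seed, {
    calib <- list(); holdout <- list(); used <- vector("list", length(trials))
    if (mode == "single") {
      if (is.null(speed)) stop("config error: single-speed mode needs 'speed'",
                               call. = FALSE)
      j0 <- which(vapply(trials, function(t) isTRUE(all.equal(t$speed, speed)),
                         TRUE))
      if (length(j0) != 1L)
        stop("data error: no unique trial at speed ", speed, call. = FALSE)
      rows <- pick(j0, n_calib)
      calib[[1]] <- as_block(j0, rows)
      used[[j0]] <- rows
    } else {
      per <- n_calib / length(trials)
      if (per != round(per))
        stop("config error: n_calib must divide evenly across trials",
             call. = FALSE)
      for (j in seq_along(trials)) {
        rows <- pick(j, per)
        calib[[j]] <- as_block(j, rows)
        used[[j]] <- rows
      }
    }
    for (j in seq_along(trials)) {
      st <- steady[[j]]
      avail <- setdiff(seq_len(nrow(st)), used[[j]])
      k <- min(n_holdout, length(avail))
      holdout[[j]] <- as_block(j, sort(sample(avail, k)))
    }
    structure(list(calib = do.call(rbind, calib),
                   holdout = do.call(rbind, holdout),
                   trials = trials, mode = mode, speed = speed, seed = seed),
              class = "hnm_dataset")
  })
}

#' @export
print.hnm_dataset <- function(x, ...) {
  cat(sprintf("<hnm_dataset> mode %s%s: %d calibration / %d held-out cycles\n",
              x$mode, if (!is.null(x$speed)) sprintf(" (%.2f m/s)", x$speed)
              else "", nrow(x$calib), nrow(x$holdout)))
  invisible(x)
}

# random-signal replacement activations for the ablation variant,
# precomputed per trial so every objective evaluation sees the same noise
.random_a2 <- function(trials, seed) {
  lapply(seq_along(trials), function(j) {
    n <- length(trials[[j]]$proc$theta)
    list(lgs = random_activation(n, seed + 2L * j),
         sol = random_activation(n, seed + 2L * j + 1L))
  })
}

# prediction residuals over the calibration cycles; returns list with the
# stacked residual vector and predicted/measured values
.calib_residuals <- function(params, dataset, constants, control,
                             a2_override = NULL) {
  cal <- dataset$calib
  pred <- list(); meas <- list()
  for (b in seq_len(nrow(cal))) {
    j <- cal$trial[b]
    proc <- dataset$trials[[j]]$proc
    ov <- if (is.null(a2_override)) NULL else a2_override[[j]]
    fw <- .forward_window(proc, cal$heel_strike_idx[b], cal$toe_off_idx[b],
                          params, constants, control, a2_override = ov)
    idx <- cal$heel_strike_idx[b]:cal$toe_off_idx[b]
    pred[[b]] <- fw$pred
    meas[[b]] <- proc$moment[idx]
  }
  pred <- unlist(pred); meas <- unlist(meas)
  list(resid = pred - meas, pred = pred, meas = meas)
}

#' Calibration objective
#'
#' Mean squared error between the model's net plantarflexion moment and the
#' benchmark moment over all stance samples of the calibration cycles:
#' `E = (1/N) * sum_j (sum_i M_i(j) - M_w(j))^2`.
#'
#' @param params an [hnm_parameters()] object.
#' @param dataset an [build_calibration_dataset()] result.
#' @param constants per-muscle constants.
#' @param control an [hnm_control()] list.
#' @return Scalar objective in (N m)^2.
#' @export
hnm_objective <- function(params, dataset,
                          constants = default_muscle_constants(),
                          control = hnm_control()) {
  r <- .calib_residuals(params, dataset, constants, control)$resid
  mean(r^2)
}

# pack/unpack the free parameter vector on the unit box ----------------------

.pack_spec <- function(bounds, variant) {
  free_delta <- variant %in% c("fused", "random_signal")
  nms <- c("A", "ltsk", "Fmax", if (free_delta) "delta")
  spec <- list()
  for (m in c("lgs", "sol"))
    for (p in nms)
      spec[[paste(m, p, sep = ".")]] <-
        c(bounds[[m]]$lower[[p]], bounds[[m]]$upper[[p]])
  spec
}

.unpack_params <- function(x, spec, variant) {
  fixed_delta <- switch(variant, semg_only = 1, us_only = 0, NULL)
  val <- function(m, p) {
    key <- paste(m, p, sep = ".")
    if (!is.null(spec[[key]])) {
      b <- spec[[key]]
      b[1] + .clip01(x[[key]]) * (b[2] - b[1])
    } else fixed_delta
  }
  hnm_parameters(
    lgs = list(A = val("lgs", "A"), ltsk = val("lgs", "ltsk"),
               Fmax = val("lgs", "Fmax"), delta = val("lgs", "delta")),
    sol = list(A = val("sol", "A"), ltsk = val("sol", "ltsk"),
               Fmax = val("sol", "Fmax"), delta = val("sol", "delta")))
}

#' Fit the neuromuscular model to benchmark moments
#'
#' Calibrates the per-muscle parameter set (shape factor `A`, tendon slack
#' length, maximal contraction force, allocation gain `delta`) by bounded
#' Levenberg-Marquardt least squares against the inverse-dynamics benchmark
#' moment over the stance phase of the calibration cycles. Parameters other
#' than `delta` are bounded at 50\%-150\% of the literature values carried in
#' `constants`; `delta` is bounded in \[0, 1\]; the start is the midpoint of
#' every box.
#'
#' @param trials a list of [gait_trial] objects (or an already-processed
#'   `gait_trials` object from [prepare_trials()]).
#' @param mode `"inter"` (2 cycles from each of the five speeds) or
#'   `"single"` (10 cycles from one speed).
#' @param speed calibration speed for single-speed mode.
#' @param variant `"fused"` (delta free), `"semg_only"` (delta fixed at 1),
#'   `"us_only"` (delta fixed at 0) or `"random_signal"` (ultrasound
#'   activation replaced by seeded uniform noise, delta free).
#' @param constants per-muscle constants, as [default_muscle_constants()].
#' @param control an [hnm_control()] list.
#' @param seed integer seed (cycle selection; noise of the random-signal
#'   variant).
#' @param n_calib,n_holdout cycles used / held out, see
#'   [build_calibration_dataset()].
#' @return An object of class `hnm_fit` with components `params`
#'   ([hnm_parameters()]), `objective` ((N m)^2), `converged`, `n_evals`,
#'   `variant`, `mode`, `dataset`, `bounds`, plus the constants/control/seed
#'   used. Standard methods: [print()], [summary()], [coef()], [predict()],
#'   [fitted()], [residuals()], [plot()], [simulate()].
#' @examples
#' \donttest{
#' trials <- forward_generate(synthetic_config(seed = 7))
#' fit <- hnm_fit(trials, mode = "inter", variant = "fused", seed = 7)
#' coef(fit)
#' metrics <- evaluate_fit(fit)
#' }
#' @export
hnm_fit <- function(trials, mode = c("inter", "single"), speed = NULL,
                    variant = c("fused", "semg_only", "us_only",
                                "random_signal"),
                    constants = default_muscle_constants(),
                    control = hnm_control(), seed = 1,
                    n_calib = 10, n_holdout = 5) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  cl <- match.call()
  if (!inherits(trials, "gait_trials"))
    trials <- prepare_trials(trials, constants, control)
  dataset <- build_calibration_dataset(trials, mode = mode, speed = speed,
                                       n_calib = n_calib,
                                       n_holdout = n_holdout,
                                       seed = seed, control = control)
  bounds <- .param_bounds(constants)
  spec <- .pack_spec(bounds, variant)
  a2_override <- if (variant == "random_signal")
    .random_a2(dataset$trials, seed * 131L + 7L) else NULL

  nres <- NULL
  fn <- function(x) {
    names(x) <- names(spec)
    p <- .unpack_params(as.list(x), spec, variant)
    r <- .calib_residuals(p, dataset, constants, control,
                          a2_override = a2_override)$resid
    r / sqrt(length(r))
  }
  x0 <- stats::setNames(rep(0.5, length(spec)), names(spec))
  opt <- minpack.lm::nls.lm(
    par = x0, lower = rep(0, length(spec)), upper = rep(1, length(spec)),
    fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = control$maxiter,
                                         ftol = control$ftol,
                                         ptol = control$ptol))
  params <- .unpack_params(as.list(stats::setNames(opt$par, names(spec))),
                           spec, variant)
  obj <- sum(opt$fvec^2)
  start_obj <- sum(fn(x0)^2)
  structure(list(params = params, objective = obj,
                 start_objective = start_obj,
                 n_evals = opt$niter, converged = opt$info %in% 1:4,
                 info = opt$info, message = opt$message,
                 variant = variant, mode = mode, speed = speed,
                 dataset = dataset, bounds = bounds,
                 a2_override = a2_override,
                 constants = constants, control = control, seed = seed,
                 call = cl),
            class = "hnm_fit")
}

#' @export
print.hnm_fit <- function(x, ...) {
  cat(sprintf("Hill-type neuromuscular model fit (%s variant, %s mode%s)\n",
              x$variant, x$mode,
              if (!is.null(x$speed)) sprintf(", %.2f m/s", x$speed) else ""))
  cat(sprintf("  objective (mean squared moment error): %.4g (N.m)^2\n",
              x$objective))
  cat(sprintf("  converged: %s after %d iterations\n", x$converged, x$n_evals))
  print(x$params)
  invisible(x)
}

#' @export
coef.hnm_fit <- function(object, ...) {
  c(unlist(object$params$lgs), unlist(object$params$sol)) |>
    stats::setNames(c(paste0("lgs.", names(object$params$lgs)),
                      paste0("sol.", names(object$params$sol))))
}

#' @export
summary.hnm_fit <- function(object, ...) {
  r <- residuals(object)
  pred <- predict(object)
  met <- tryCatch(evaluate_fit(object, pred = pred), error = function(e) NULL)
  structure(list(fit = object, calib_rmse = sqrt(mean(r^2)),
                 n_calib_samples = length(r), holdout = met),
            class = "summary.hnm_fit")
}

#' @export
print.summary.hnm_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  calibration RMSE: %.3f N.m over %d stance samples\n",
              x$calib_rmse, x$n_calib_samples))
  if (!is.null(x$holdout)) {
    cat("  held-out prediction metrics per speed:\n")
    print(x$holdout, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
residuals.hnm_fit <- function(object, ...) {
  .calib_residuals(object$params, object$dataset, object$constants,
                   object$control, a2_override = object$a2_override)$resid
}

#' @export
fitted.hnm_fit <- function(object, ...) {
  .calib_residuals(object$params, object$dataset, object$constants,
                   object$control, a2_override = object$a2_override)$pred
}

#' Predict the net plantarflexion moment on held-out cycles
#'
#' Runs the calibrated model over stance cycles that were not part of the
#' calibration set (or over any cycle table supplied) and returns the
#' predicted and benchmark moment per sample.
#'
#' @param object an [hnm_fit] object.
#' @param newdata optional processed `gait_trials` object; defaults to the
#'   trials stored in the fit.
#' @param cycles optional cycle table (`trial`, `speed`, `heel_strike_idx`,
#'   `toe_off_idx`); defaults to the held-out cycles of the fit's dataset.
#' @param ... unused.
#' @return A data frame with one row per stance sample: `speed`, `cycle`,
#'   `phase` (0-1 within stance), `pred`, `meas` (N m; `meas` is `NA` when the
#'   benchmark channel is absent).
#' @export
predict.hnm_fit <- function(object, newdata = NULL, cycles = NULL, ...) {
  trials <- if (is.null(newdata)) object$dataset$trials else newdata
  if (!inherits(trials, "gait_trials"))
    trials <- prepare_trials(trials, object$constants, object$control)
  if (is.null(cycles)) {
    if (is.null(newdata)) cycles <- object$dataset$holdout
    else {
      cycles <- do.call(rbind, lapply(seq_along(trials), function(j) {
        st <- trials[[j]]$proc$stance
        data.frame(trial = j, speed = trials[[j]]$speed,
                   heel_strike_idx = st$heel_strike_idx,
                   toe_off_idx = st$toe_off_idx)
      }))
    }
  }
  ov <- if (!is.null(object$a2_override) && is.null(newdata))
    object$a2_override
  else if (object$variant == "random_signal")
    .random_a2(trials, object$seed * 131L + 7L)
  else NULL

  out <- list()
  for (b in seq_len(nrow(cycles))) {
    j <- cycles$trial[b]
    proc <- trials[[j]]$proc
    hs <- cycles$heel_strike_idx[b]; to <- cycles$toe_off_idx[b]
    fw <- .forward_window(proc, hs, to, object$params, object$constants,
                          object$control,
                          a2_override = if (is.null(ov)) NULL else ov[[j]])
    idx <- hs:to
    out[[b]] <- data.frame(
      speed = cycles$speed[b], cycle = b,
      phase = (idx - hs) / (to - hs),
      pred = fw$pred,
      meas = if (is.null(proc$moment)) NA_real_ else proc$moment[idx])
  }
  do.call(rbind, out)
}

#' @export
plot.hnm_fit <- function(x, ...) {
  pr <- predict(x)
  speeds <- sort(unique(pr$speed))
  op <- graphics::par(mfrow = c(1, length(speeds)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (sp in speeds) {
    d <- pr[pr$speed == sp, ]
    graphics::plot(d$phase * 100, d$meas, col = "grey60", pch = 16,
                   cex = 0.3, xlab = "stance phase [%]",
                   ylab = "net PF moment [N.m]",
                   main = sprintf("%.2f m/s", sp), ...)
    graphics::points(d$phase * 100, d$pred, col = "firebrick", pch = 16,
                     cex = 0.3)
  }
  invisible(x)
}

#' Simulate moment observations from a fitted model
#'
#' Draws simulated benchmark-moment observations at the calibration samples:
#' the fitted model's predicted moment plus Gaussian noise at the residual
#' standard deviation.
#'
#' @param object an [hnm_fit] object.
#' @param nsim number of simulated series.
#' @param seed integer seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns, one row per calibration sample.
#' @export
simulate.hnm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  pred <- fitted(object)
  sdr <- stats::sd(residuals(object))
  sim <- function() pred + stats::rnorm(length(pred), 0, sdr)
  out <- if (is.null(seed)) replicate(nsim, sim())
  else .with_seed(seed, replicate(nsim, sim()))
  as.data.frame(out) |> stats::setNames(paste0("sim_", seq_len(nsim)))
}
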