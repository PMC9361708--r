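#' Moment prediction accuracy metrics
#'
#' Root mean square error between predicted and benchmark moment, plus the
#' two normalizations used to compare across subjects: `n_rmse` (percent of
#' the individual peak net plantarflexion moment) and `bm_rmse` (per kg of
#' body mass), and the coefficient of determination about the benchmark mean.
#'
#' @param pred,truth numeric vectors of equal length (>= 2), N m.
#' @param peak_moment individual peak net plantarflexion moment, N m (> 0).
#' @param body_mass body mass in kg (> 0).
#' @return A list of class `metric_bundle`: `rmse` (N m), `n_rmse` (percent),
#'   `bm_rmse` (N m/kg), `r2`.
#' @examples
#' hnm_metrics(c(1, 2, 3) + 10, c(1, 2, 3), peak_moment = 100, body_mass = 80)
#' @export
hnm_metrics <- function(pred, truth, peak_moment, body_mass) {
  pred <- .series_values(pred); truth <- .series_values(truth)
  if (length(pred) != length(truth) || length(pred) < 2)
    stop("alignment error: need equal-length series of length >= 2",
         call. = FALSE)
  if (peak_moment <= 0 || body_mass <= 0)
    stop("config error: peak_moment and body_mass must be positive",
         call. = FALSE)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0)
    stop("data error: zero-variance benchmark, R^2 undefined", call. = FALSE)
  rmse <- sqrt(mean((pred - truth)^2))
  structure(list(rmse = rmse, n_rmse = 100 * rmse / peak_moment,
                 bm_rmse = rmse / body_mass,
                 r2 = 1 - sum((pred - truth)^2) / ss_tot),
            class = "metric_bundle")
}

#' @export
print.metric_bundle <- function(x, ...) {
  cat(sprintf("RMSE %.3f N.m | N-RMSE %.2f%% | BM-RMSE %.4f N.m/kg | R2 %.4f\n",
              x$rmse, x$n_rmse, x$bm_rmse, x$r2))
  invisible(x)
}

#' Individual peak net plantarflexion moment
#'
#' The maximum benchmark moment across the stance samples of all retained
#' cycles of all speeds; used as the subject-constant normalizer of
#' `n_rmse`, matching the cross-speed task-peak normalization of the sEMG.
#'
#' @param trials processed trials from [prepare_trials()].
#' @return Scalar peak moment in N m.
#' @export
peak_pf_moment <- function(trials) {
  mx <- -Inf
  for (tr in trials) {
    if (is.null(tr$proc$moment)) next
    st <- tr$proc$stance
    for (b in seq_len(nrow(st)))
      mx <- max(mx, tr$proc$moment[st$heel_strike_idx[b]:st$toe_off_idx[b]])
  }
  if (!is.finite(mx))
    stop("data error: no benchmark moment available", call. = FALSE)
  mx
}

#' Held-out prediction metrics of a fit, per speed
#'
#' Convenience wrapper: predicts on the fit's held-out cycles and computes
#' [hnm_metrics()] per prediction speed, normalizing by the subject's peak
#' moment and body mass.
#'
#' @param fit an [hnm_fit] object.
#' @param pred optional precomputed prediction table from [predict.hnm_fit()].
#' @return A data frame with one row per speed: `speed`, `n_samples`, `rmse`,
#'   `n_rmse`, `bm_rmse`, `r2`.
#' @export
evaluate_fit <- function(fit, pred = NULL) {
  if (is.null(pred)) pred <- predict(fit)
  trials <- fit$dataset$trials
  peak <- peak_pf_moment(trials)
  mass <- trials[[1]]$body_mass
  speeds <- sort(unique(pred$speed))
  do.call(rbind, lapply(speeds, function(sp) {
    d <- pred[pred$speed == sp, ]
    m <- hnm_metrics(d$pred, d$meas, peak, mass)
    data.frame(speed = sp, n_samples = nrow(d), rmse = m$rmse,
               n_rmse = m$n_rmse, bm_rmse = m$bm_rmse, r2 = m$r2)
  }))
}

#' Per-cycle correlation between neuromuscular features and the moment
#'
#' For every stance cycle of every trial, the Pearson correlation between
#' each neuromuscular feature (LGS/SOL sEMG envelope, LGS/SOL muscle
#' thickness) and the benchmark net plantarflexion moment over that cycle.
#' Correlations are aggregated per feature and speed through the Fisher
#' transformation: values are clipped to +/-(1 - 1e-9), transformed with
#' `atanh`, averaged in z-space and the mean is reported back through `tanh`;
#' the SD is reported in z-space (and back-transformed for reference).
#'
#' @param trials processed trials from [prepare_trials()].
#' @return A data frame with one row per speed and feature: `speed`,
#'   `feature`, `n_cycles`, `mean_r`, `sd_z`, `sd_r_approx`.
#' @export
correlation_table <- function(trials) {
  feats <- c(semg_lgs = "u_lgs", semg_sol = "u_sol",
             mt_lgs = "a2_lgs", mt_sol = "a2_sol")
  rows <- list()
  for (tr in trials) {
    proc <- tr$proc
    if (is.null(proc$moment)) next
    st <- proc$stance
    for (b in seq_len(nrow(st))) {
      idx <- st$heel_strike_idx[b]:st$toe_off_idx[b]
      mom <- proc$moment[idx]
      for (f in names(feats)) {
        x <- proc[[feats[[f]]]][idx]
        if (stats::sd(x) == 0 || stats::sd(mom) == 0) next  # skip, degenerate
        r <- stats::cor(x, mom)
        rows[[length(rows) + 1L]] <-
          data.frame(speed = tr$speed, feature = f, r = r)
      }
    }
  }
  if (!length(rows)) stop("data error: no usable stance cycles", call. = FALSE)
  d <- do.call(rbind, rows)
  d$z <- atanh(pmin(pmax(d$r, -(1 - 1e-9)), 1 - 1e-9))
  agg <- list()
  for (sp in sort(unique(d$speed)))
    for (f in unique(d$feature)) {
      z <- d$z[d$speed == sp & d$feature == f]
      if (!length(z)) next
      agg[[length(agg) + 1L]] <- data.frame(
        speed = sp, feature = f, n_cycles = length(z),
        mean_r = tanh(mean(z)), sd_z = stats::sd(z),
        sd_r_approx = tanh(mean(z) + stats::sd(z)) - tanh(mean(z)))
    }
  do.call(rbind, agg)
}

#' Compare model variants across calibration modes and speeds
#'
#' Descriptive summary of a grid of metric results: per-variant means, the
#' percent change of each variant relative to the sEMG-only and
#' ultrasound-only baselines, and the across-speed SD per calibration mode
#' (a robustness proxy).
#'
#' @param results data frame with columns `variant`, `mode`, `speed` and the
#'   metric columns `rmse`, `n_rmse`, `bm_rmse`, `r2` (one row per cell; a
#'   complete grid is expected, missing cells yield `NA` markers).
#' @param metric which metric to summarize (default `"n_rmse"`).
#' @return A list with `by_variant` (means and percent changes vs the
#'   unimodal baselines) and `spread` (across-speed SD per variant and mode).
#' @export
compare_variants <- function(results, metric = "n_rmse") {
  stopifnot(metric %in% names(results))
  v_mean <- tapply(results[[metric]], results$variant, mean)
  pct <- function(v, ref)
    if (ref %in% names(v_mean)) 100 * (v - v_mean[[ref]]) / v_mean[[ref]]
    else NA_real_
  by_variant <- data.frame(
    variant = names(v_mean), mean = as.numeric(v_mean),
    pct_vs_semg = vapply(v_mean, pct, 1, ref = "semg_only"),
    pct_vs_us = vapply(v_mean, pct, 1, ref = "us_only"),
    row.names = NULL)
  cells <- unique(results[, c("variant", "mode")])
  spread <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    d <- results[results$variant == cells$variant[i] &
                   results$mode == cells$mode[i], ]
    data.frame(variant = cells$variant[i], mode = cells$mode[i],
               n_speeds = nrow(d),
               across_speed_sd = if (nrow(d) > 1) stats::sd(d[[metric]])
               else NA_real_)
  }))
  list(by_variant = by_variant, spread = spread)
}
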