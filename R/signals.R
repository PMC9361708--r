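#' sEMG linear envelope
#'
#' Band-pass filters a raw sEMG channel, full-wave rectifies it and low-pass
#' filters the result into a linear envelope. All filters are Butterworth,
#' applied forward-backward (zero phase, no group delay).
#'
#' @param raw_semg raw sEMG channel, a [uniform_series] or numeric vector.
#' @param fs sampling rate in Hz (taken from the series if not given).
#' @param band_lo,band_hi band-pass corner frequencies in Hz. Defaults 20 and
#'   450 Hz, the conventional surface-EMG band.
#' @param env_cutoff low-pass cut-off of the envelope stage in Hz (default 6).
#' @param order Butterworth order (default 4).
#' @return Nonnegative envelope on the same grid as the input.
#' @seealso [normalize_envelope()], [filter_mt()]
#' @export
bandpass_envelope <- function(raw_semg, fs = NULL, band_lo = 20, band_hi = 450,
                              env_cutoff = 6, order = 4) {
  fs <- .series_fs(raw_semg, fs)
  x <- .series_values(raw_semg)
  if (!all(is.finite(x))) stop("data error: non-finite sEMG input", call. = FALSE)
  if (fs <= 2 * band_hi)
    stop("invalid-rate: fs must exceed twice the upper band edge", call. = FALSE)
  if (band_lo >= band_hi) stop("band_lo must be below band_hi", call. = FALSE)
  if (env_cutoff >= band_lo)
    stop("envelope cut-off must lie below the band", call. = FALSE)
  bp <- .butter_coeffs(order, c(band_lo, band_hi), fs, "pass")
  lp <- .butter_coeffs(order, env_cutoff, fs, "low")
  env <- .zerophase_filter(lp$b, lp$a, abs(.zerophase_filter(bp$b, bp$a, x)))
  .series_rewrap(pmax(env, 0), raw_semg)
}

#' Normalize an sEMG envelope to the task peak
#'
#' Divides the envelope by the subject's task peak (the maximum processed sEMG
#' value across all retained trials of all speeds, constant per subject) and
#' clips to \[0, 1\].
#'
#' @param envelope envelope series or numeric vector.
#' @param task_peak positive scalar, the cross-speed task peak.
#' @return Normalized envelope `u` in \[0, 1\].
#' @export
normalize_envelope <- function(envelope, task_peak) {
  if (!is.numeric(task_peak) || length(task_peak) != 1L ||
      !is.finite(task_peak) || task_peak <= 0)
    stop("config error: 'task_peak' must be a single positive number",
         call. = FALSE)
  .series_rewrap(.clip01(.series_values(envelope) / task_peak), envelope,
                 units = "")
}

#' Low-pass filter a muscle-thickness trace
#'
#' Zero-phase Butterworth low-pass of an ultrasound-derived muscle-thickness
#' time series (default cut-off 30 Hz).
#'
#' @param mt_raw muscle-thickness series (mm) or numeric vector.
#' @param fs sampling rate in Hz (taken from the series if not given).
#' @param cutoff low-pass cut-off in Hz.
#' @param order Butterworth order (default 4).
#' @return Smoothed series on the same grid.
#' @export
filter_mt <- function(mt_raw, fs = NULL, cutoff = 30, order = 4) {
  fs <- .series_fs(mt_raw, fs)
  x <- .series_values(mt_raw)
  if (!all(is.finite(x))) stop("data error: non-finite input", call. = FALSE)
  if (fs <= 2 * cutoff)
    stop("invalid-rate: fs must exceed twice the cut-off", call. = FALSE)
  lp <- .butter_coeffs(order, cutoff, fs, "low")
  .series_rewrap(.zerophase_filter(lp$b, lp$a, x), mt_raw)
}

#' Resample a channel to the model grid
#'
#' Rate conversion of an analog-rate channel (typically 1000 Hz) onto the
#' model grid (default 100 Hz): a zero-phase Butterworth anti-alias low-pass
#' at 45\% of the target rate, then exact decimation for integer rate ratios
#' or interpolation onto the new time grid otherwise. The first sample keeps
#' its time stamp, so channels stay aligned.
#'
#' @param x series or numeric vector.
#' @param fs_out target rate in Hz.
#' @param fs input rate in Hz (taken from the series if not given).
#' @return Resampled values; a [uniform_series] at `fs_out` when the input was
#'   a series.
#' @export
resample_series <- function(x, fs_out, fs = NULL) {
  fs <- .series_fs(x, fs)
  v <- .series_values(x)
  if (isTRUE(all.equal(fs, fs_out))) return(x)
  if (fs_out < fs) {
    lp <- .butter_coeffs(8, 0.45 * fs_out, fs, "low")
    v <- .zerophase_filter(lp$b, lp$a, v)
  }
  ratio <- fs / fs_out
  y <- if (abs(ratio - round(ratio)) < 1e-9) {
    v[seq(1, length(v), by = as.integer(round(ratio)))]
  } else {
    t_in <- (seq_along(v) - 1) / fs
    t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
    stats::approx(t_in, v, xout = t_out)$y
  }
  if (is_uniform_series(x))
    uniform_series(y, fs = fs_out, t0 = x$t0, units = x$units)
  else y
}

#' Segment stance phases from vertical ground reaction force
#'
#' Detects foot contacts by thresholding the vertical GRF: an upward crossing
#' marks heel strike, a downward crossing marks toe off. Contacts shorter than
#' `min_duration` and contacts truncated by the record edges are discarded.
#'
#' @param grf_vertical vertical GRF series (N) or numeric vector.
#' @param fs sampling rate in Hz (taken from the series if not given).
#' @param threshold contact threshold in N (default 20, a common gait-lab
#'   convention).
#' @param min_duration minimum stance duration in seconds (default 0.2).
#' @return A data frame with one row per stance cycle: `heel_strike_idx`,
#'   `toe_off_idx` (sample indices, heel strike strictly before toe off) and
#'   `duration_s`. Zero rows (with a warning) if no contact is found.
#' @examples
#' grf <- rep(c(rep(0, 40), rep(800, 60)), 3)
#' segment_stance(grf, fs = 100)
#' @export
segment_stance <- function(grf_vertical, fs = NULL, threshold = 20,
                           min_duration = 0.2) {
  fs <- .series_fs(grf_vertical, fs)
  g <- .series_values(grf_vertical)
  above <- g > threshold
  rises <- which(diff(c(FALSE, above)) == 1L)
  falls <- which(diff(c(above, FALSE)) == -1L)
  # drop contacts truncated at either edge
  keep <- rep(TRUE, length(rises))
  if (length(rises)) {
    keep[rises == 1L] <- FALSE
    keep[falls == length(g)] <- FALSE
  }
  rises <- rises[keep]; falls <- falls[keep]
  dur <- (falls - rises) / fs
  ok <- dur >= min_duration
  out <- data.frame(heel_strike_idx = rises[ok], toe_off_idx = falls[ok],
                    duration_s = dur[ok])
  if (nrow(out) == 0L)
    warning("no stance cycle detected", call. = FALSE)
  out
}
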