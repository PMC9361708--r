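#' Recursive neural-activation filter coefficients
#'
#' The discrete second-order recursive filter mapping the normalized sEMG
#' envelope to neural activation is parameterized by two real poles
#' `gamma1`, `gamma2` with magnitude below 1. The coefficients satisfy
#' `beta1 = gamma1 + gamma2`, `beta2 = gamma1 * gamma2` and
#' `alpha - beta1 - beta2 = 1`, which pins the steady-state gain at exactly 1
#' (a sustained envelope level is reproduced in the neural activation).
#'
#' @param gamma1,gamma2 filter poles, `abs(.) < 1`.
#' @return A list with `alpha`, `beta1`, `beta2`.
#' @examples
#' recursion_coeffs(0.5, 0.5) # alpha 2.25, beta1 1.0, beta2 0.25
#' @export
recursion_coeffs <- function(gamma1, gamma2) {
  if (abs(gamma1) >= 1 || abs(gamma2) >= 1)
    stop("stability error: pole magnitudes must be < 1", call. = FALSE)
  beta1 <- gamma1 + gamma2
  beta2 <- gamma1 * gamma2
  list(alpha = 1 + beta1 + beta2, beta1 = beta1, beta2 = beta2)
}

#' Parameters of the neural-activation stage
#'
#' Bundles the fixed settings of the sEMG-to-neural-activation filter: the
#' two poles, and the electromechanical delay `tau` between sEMG onset and
#' force production (30-120 ms; rounded to whole samples at the model rate).
#' These are held fixed during calibration; only the nonlinear shape factor
#' `A` is calibrated.
#'
#' @param gamma1,gamma2 filter poles (defaults 0.5, 0.5: stable, unit DC gain).
#' @param tau electromechanical delay in seconds (default 0.040).
#' @return An object of class `activation_filter_params`.
#' @export
activation_filter_params <- function(gamma1 = 0.5, gamma2 = 0.5, tau = 0.040) {
  if (abs(gamma1) >= 1 || abs(gamma2) >= 1)
    stop("stability error: pole magnitudes must be < 1", call. = FALSE)
  if (tau < 0.030 - 1e-12 || tau > 0.120 + 1e-12)
    stop("config error: 'tau' must lie in [0.030, 0.120] s", call. = FALSE)
  structure(list(gamma1 = gamma1, gamma2 = gamma2, tau = tau),
            class = "activation_filter_params")
}

#' Neural activation from the normalized sEMG envelope
#'
#' Applies the delayed second-order recursive filter
#' `N(k) = alpha * u(k - d) - beta1 * N(k-1) - beta2 * N(k-2)` with the delay
#' `d = round(tau * fs)` samples, zero initial history, and output clipped to
#' \[0, 1\].
#'
#' @param u normalized envelope in \[0, 1\] (series or numeric vector).
#' @param params an [activation_filter_params()] object.
#' @param fs sampling rate in Hz (taken from the series if not given).
#' @return Neural activation on the same grid, in \[0, 1\].
#' @export
neural_activation <- function(u, params = activation_filter_params(),
                              fs = NULL) {
  fs <- .series_fs(u, fs)
  x <- .series_values(u)
  if (any(x < -1e-9) || any(x > 1 + 1e-9))
    stop("data error: 'u' must lie in [0, 1]", call. = FALSE)
  cf <- recursion_coeffs(params$gamma1, params$gamma2)
  d <- as.integer(round(params$tau * fs))
  xd <- if (d > 0) c(rep(0, d), x)[seq_along(x)] else x
  n <- as.numeric(stats::filter(cf$alpha * xd, c(-cf$beta1, -cf$beta2),
                                method = "recursive", init = c(0, 0)))
  .series_rewrap(.clip01(n), u)
}

#' sEMG-derived muscle activation (nonlinear shaping)
#'
#' Maps neural activation to muscle activation through
#' `a1 = (exp(A * N) - 1) / (exp(A) - 1)`, with shape factor `A` in
#' \[-3, 0\]; `A = 0` is the linear limit `a1 = N` (evaluated analytically).
#'
#' @param N neural activation in \[0, 1\] (series or numeric vector).
#' @param A shape factor, between -3 (most nonlinear) and 0 (linear).
#' @return Muscle activation `a1` in \[0, 1\], monotone in `N`.
#' @export
semg_activation <- function(N, A) {
  if (A < -3 - 1e-12 || A > 1e-12)
    stop("config error: shape factor 'A' must lie in [-3, 0]", call. = FALSE)
  x <- .series_values(N)
  a1 <- if (abs(A) < 1e-12) x else (exp(A * x) - 1) / (exp(A) - 1)
  .series_rewrap(.clip01(a1), N)
}

#' Ultrasound-derived muscle activation
#'
#' Normalizes a muscle-thickness trace to the subject-constant bounds
#' `mt_min` (complete rest) and `mt_max` (task-specific maximum voluntary
#' contraction): `a2 = (MT - mt_min) / (mt_max - mt_min)`, clipped to \[0, 1\].
#'
#' @param mt muscle-thickness trace in mm (series or numeric vector).
#' @param mt_min,mt_max subject-constant thickness bounds in mm,
#'   `mt_max > mt_min > 0`; held fixed across walking speeds.
#' @return Activation `a2` in \[0, 1\].
#' @export
us_activation <- function(mt, mt_min, mt_max) {
  if (!is.finite(mt_min) || !is.finite(mt_max) || mt_max <= mt_min ||
      mt_min <= 0)
    stop("config error: require mt_max > mt_min > 0", call. = FALSE)
  .series_rewrap(.clip01((.series_values(mt) - mt_min) / (mt_max - mt_min)),
                 mt, units = "")
}

#' Fused muscle activation
#'
#' Convex combination of the sEMG-derived and ultrasound-derived activations,
#' `a = delta * a1 + (1 - delta) * a2`. `delta = 1` gives the sEMG-only
#' variant, `delta = 0` the ultrasound-only variant.
#'
#' @param a1,a2 activation series (same grid, values in \[0, 1\]).
#' @param delta allocation gain in \[0, 1\].
#' @return Fused activation on the same grid.
#' @export
fuse_activation <- function(a1, a2, delta) {
  if (delta < 0 || delta > 1)
    stop("config error: 'delta' must lie in [0, 1]", call. = FALSE)
  .check_same_grid(a1, a2)
  .series_rewrap(delta * .series_values(a1) + (1 - delta) * .series_values(a2),
                 a1)
}

#' Random-signal replacement for the ultrasound activation
#'
#' Control condition for ablation: a seeded uniform \[0, 1\] sequence that can
#' stand in for the ultrasound-derived activation, reproducing the enlarged
#' solution space of the fused model without its information content.
#'
#' @param n number of samples.
#' @param seed integer seed (the sequence is fully determined by it).
#' @return Numeric vector of `n` independent uniform \[0, 1\] draws.
#' @export
random_activation <- function(n, seed) {
  .with_seed(seed, stats::runif(n))
}
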