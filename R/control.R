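#' Control settings for the neuromuscular model pipeline
#'
#' Collects the fixed (non-calibrated) settings: neural-activation filter,
#' angle convention, muscle curve constants, preprocessing and stance
#' segmentation settings, and optimizer tolerances.
#'
#' @param activation an [activation_filter_params()] object (poles and
#'   electromechanical delay; fixed during calibration).
#' @param q_neutral included segment angle at neutral ankle position, rad.
#'   The model joint angle is `q = q_neutral + theta` with `theta` the
#'   anatomical ankle angle, dorsiflexion positive, so dorsiflexion lengthens
#'   the plantarflexor path.
#' @param curves a [muscle_curves()] list.
#' @param convention moment-arm convention, see [moment_arm()].
#' @param fs_model model grid rate in Hz (default 100, the kinematics rate).
#' @param semg_band,env_cutoff,mt_cutoff,filter_order preprocessing filter
#'   settings in Hz (see [bandpass_envelope()], [filter_mt()]).
#' @param stance_threshold,min_stance stance segmentation settings
#'   (see [segment_stance()]).
#' @param runin number of samples solved before each stance cycle so the
#'   fascicle-velocity state settles before the scored samples (default 15).
#' @param steady_tol relative tolerance on cycle duration about the trial
#'   median for a cycle to count as "steady" (default 0.10).
#' @param maxiter,ftol,ptol optimizer settings for the bounded
#'   Levenberg-Marquardt fit.
#' @return A list of class `hnm_control`.
#' @export
hnm_control <- function(activation = activation_filter_params(),
                        q_neutral = pi / 2,
                        curves = muscle_curves(),
                        convention = "derivative",
                        fs_model = 100,
                        semg_band = c(20, 450), env_cutoff = 6,
                        mt_cutoff = 30, filter_order = 4,
                        stance_threshold = 20, min_stance = 0.2,
                        runin = 15, steady_tol = 0.10,
                        maxiter = 200, ftol = 1e-8, ptol = 1e-8) {
  structure(list(activation = activation, q_neutral = q_neutral,
                 curves = curves, convention = convention,
                 fs_model = fs_model, semg_band = semg_band,
                 env_cutoff = env_cutoff, mt_cutoff = mt_cutoff,
                 filter_order = filter_order,
                 stance_threshold = stance_threshold, min_stance = min_stance,
                 runin = runin, steady_tol = steady_tol,
                 maxiter = maxiter, ftol = ftol, ptol = ptol),
            class = "hnm_control")
}

#' Calibratable parameter set of the model
#'
#' The calibrated parameters, per muscle: nonlinear shape factor `A`
#' (\[-3, 0\]), tendon slack length `ltsk` (m), maximal contraction force
#' `Fmax` (N) and activation allocation gain `delta` (\[0, 1\]; 1 = sEMG only,
#' 0 = ultrasound only).
#'
#' @param lgs,sol named lists with entries `A`, `ltsk`, `Fmax`, `delta`.
#' @return An object of class `hnm_parameters`.
#' @examples
#' hnm_parameters(lgs = list(A = -2, ltsk = 0.35, Fmax = 600, delta = 0.6),
#'                sol = list(A = -1, ltsk = 0.23, Fmax = 2800, delta = 0.5))
#' @export
hnm_parameters <- function(lgs, sol) {
  check <- function(p, nm) {
    need <- c("A", "ltsk", "Fmax", "delta")
    if (!all(need %in% names(p)))
      stop("config error: parameters for ", nm, " need ",
           paste(need, collapse = ", "), call. = FALSE)
    if (p$A < -3 - 1e-9 || p$A > 1e-9)
      stop("config error: A must lie in [-3, 0]", call. = FALSE)
    if (p$delta < 0 || p$delta > 1)
      stop("config error: delta must lie in [0, 1]", call. = FALSE)
    if (p$ltsk <= 0 || p$Fmax <= 0)
      stop("config error: ltsk and Fmax must be positive", call. = FALSE)
    p[need]
  }
  structure(list(lgs = check(lgs, "lgs"), sol = check(sol, "sol")),
            class = "hnm_parameters")
}

#' @export
print.hnm_parameters <- function(x, ...) {
  cat("Hill-type model parameters (per muscle):\n")
  m <- rbind(lgs = unlist(x$lgs), sol = unlist(x$sol))
  print(round(m, 4))
  invisible(x)
}

# parameter box: A within [0.5, 1.5] x literature (intersected with [-3, 0]),
# ltsk and Fmax within [0.5, 1.5] x literature, delta within [0, 1]
.param_bounds <- function(constants) {
  per <- function(cst) {
    a_lo <- max(-3, 1.5 * cst$lit_A)
    a_hi <- min(0, 0.5 * cst$lit_A)
    list(lower = c(A = a_lo, ltsk = 0.5 * cst$lit_ltsk,
                   Fmax = 0.5 * cst$lit_Fmax, delta = 0),
         upper = c(A = a_hi, ltsk = 1.5 * cst$lit_ltsk,
                   Fmax = 1.5 * cst$lit_Fmax, delta = 1))
  }
  list(lgs = per(constants$lgs), sol = per(constants$sol))
}

.param_midpoint <- function(bounds) {
  mid <- function(b) as.list((b$lower + b$upper) / 2)
  hnm_parameters(lgs = stats::setNames(mid(bounds$lgs), c("A", "ltsk", "Fmax", "delta")),
                 sol = stats::setNames(mid(bounds$sol), c("A", "ltsk", "Fmax", "delta")))
}
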