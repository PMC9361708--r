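#' Run the neuromuscular model forward
#'
#' Full forward evaluation on the model grid: sEMG-derived activation (neural
#' filter + nonlinear shaping), ultrasound-derived activation, convex fusion,
#' musculotendon geometry from the ankle angle, per-sample tendon-muscle
#' equilibrium for both muscles, and the net plantarflexion moment.
#'
#' @param theta anatomical ankle angle in rad (dorsiflexion positive), numeric
#'   vector on the model grid.
#' @param u_lgs,u_sol normalized sEMG envelopes in \[0, 1\].
#' @param a2_lgs,a2_sol ultrasound-derived activations in \[0, 1\].
#' @param params an [hnm_parameters()] object.
#' @param constants per-muscle constants, as [default_muscle_constants()].
#' @param control an [hnm_control()] list.
#' @param fs sampling rate in Hz (default `control$fs_model`).
#' @return A list: `moment` (net plantarflexion moment, N m), `a` (fused
#'   activations per muscle), `states` (per-muscle solved state data frames),
#'   `r` (per-muscle moment-arm vectors, m).
#' @export
hnm_forward <- function(theta, u_lgs, u_sol, a2_lgs, a2_sol, params,
                        constants = default_muscle_constants(),
                        control = hnm_control(), fs = control$fs_model) {
  N <- list(
    lgs = .series_values(neural_activation(u_lgs, control$activation, fs = fs)),
    sol = .series_values(neural_activation(u_sol, control$activation, fs = fs)))
  a2 <- list(lgs = .series_values(a2_lgs), sol = .series_values(a2_sol))
  .forward_core(as.numeric(theta), N, a2, params, constants, control, fs)
}

# forward evaluation from precomputed neural activations (calibration path)
.forward_core <- function(theta, N, a2, params, constants, control, fs) {
  q <- control$q_neutral + theta
  dt <- 1 / fs
  states <- list(); rr <- list(); act <- list()
  for (m in c("lgs", "sol")) {
    p <- params[[m]]
    cst <- constants[[m]]
    a1 <- semg_activation(N[[m]], p$A)
    a <- p$delta * a1 + (1 - p$delta) * a2[[m]]
    lmt <- mtu_length(q, cst)
    r <- moment_arm(q, cst, convention = control$convention)
    states[[m]] <- muscle_forward(lmt, a, cst, ltsk = p$ltsk, Fmax = p$Fmax,
                                  dt = dt, curves = control$curves)
    rr[[m]] <- r
    act[[m]] <- a
  }
  list(moment = joint_moment(states, rr), a = act, states = states, r = rr)
}

# forward over one stance window (with mechanical run-in) of a processed trial
# returns predicted moment at the stance samples only
.forward_window <- function(proc, hs, to, params, constants, control,
                            a2_override = NULL) {
  r0 <- max(1L, hs - control$runin)
  idx <- r0:to
  N <- list(lgs = proc$N_lgs[idx], sol = proc$N_sol[idx])
  a2 <- if (is.null(a2_override))
    list(lgs = proc$a2_lgs[idx], sol = proc$a2_sol[idx])
  else list(lgs = a2_override$lgs[idx], sol = a2_override$sol[idx])
  fw <- .forward_core(proc$theta[idx], N, a2, params, constants, control,
                      proc$fs)
  keep <- (hs - r0 + 1L):(to - r0 + 1L)
  list(pred = fw$moment[keep],
       resid_max = max(abs(unlist(lapply(fw$states, `[[`, "resid")))),
       states = lapply(fw$states, function(s) s[keep, , drop = FALSE]))
}
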