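#' Anatomical and physiological constants of one muscle-tendon unit
#'
#' Per-muscle constants consumed by the geometry and contraction models. The
#' geometry is a two-segment construction in the sagittal plane: `l_OA` is the
#' distance from the ankle rotation centre to the proximal osteotendinous
#' junction (near the knee), `l_OB` to the distal junction at the heel; the
#' included angle between the two segments is the model joint angle `q`.
#' Literature reference values (`lit_A`, `lit_ltsk`, `lit_Fmax`) anchor the
#' calibration bounds at 50\%-150\%.
#'
#' @param name muscle label, e.g. `"lgs"` or `"sol"`.
#' @param l_OA,l_OB segment lengths in m.
#' @param phi0 optimal pennation angle in rad (at optimal fascicle length).
#' @param l_mo0 optimal fascicle length (m) at task-specific maximum voluntary
#'   contraction.
#' @param v_max maximal fascicle shortening velocity in m/s; default
#'   `10 * l_mo0` per second (common Hill-model convention).
#' @param lambda rate of increase of optimal fascicle length as activation
#'   drops (dimensionless, default 0.15).
#' @param mt_min,mt_max subject-constant muscle-thickness bounds in mm.
#' @param lit_A,lit_ltsk,lit_Fmax literature values of the calibrated shape
#'   factor, tendon slack length (m) and maximal contraction force (N).
#' @return An object of class `muscle_constants`.
#' @seealso [default_muscle_constants()]
#' @export
muscle_constants <- function(name, l_OA, l_OB, phi0, l_mo0, v_max = NULL,
                             lambda = 0.15, mt_min, mt_max,
                             lit_A = -1.5, lit_ltsk, lit_Fmax) {
  if (any(c(l_OA, l_OB, l_mo0, lit_ltsk, lit_Fmax) <= 0))
    stop("config error: lengths and forces must be positive", call. = FALSE)
  if (phi0 < 0 || phi0 >= pi / 2)
    stop("config error: phi0 must lie in [0, pi/2)", call. = FALSE)
  if (lambda < 0) stop("config error: lambda must be >= 0", call. = FALSE)
  if (is.null(v_max)) v_max <- 10 * l_mo0
  if (v_max <= 0) stop("config error: v_max must be positive", call. = FALSE)
  if (mt_max <= mt_min || mt_min <= 0)
    stop("config error: require mt_max > mt_min > 0", call. = FALSE)
  structure(list(name = name, l_OA = l_OA, l_OB = l_OB, phi0 = phi0,
                 l_mo0 = l_mo0, v_max = v_max, lambda = lambda,
                 mt_min = mt_min, mt_max = mt_max, lit_A = lit_A,
                 lit_ltsk = lit_ltsk, lit_Fmax = lit_Fmax),
            class = "muscle_constants")
}

#' Default plantarflexor constants
#'
#' Constants for the lateral gastrocnemius (LGS) and soleus (SOL) in the
#' range of generic scaled musculoskeletal models: LGS with a long proximal
#' segment (origin above the knee) and small pennation; SOL with a mid-shank
#' origin, shorter fascicles, larger pennation and a much larger maximal
#' force.
#'
#' @return A named list with elements `lgs` and `sol`, each a
#'   [muscle_constants()] object.
#' @export
default_muscle_constants <- function() {
  list(
    lgs = muscle_constants("lgs", l_OA = 0.400, l_OB = 0.060, phi0 = 0.14,
                           l_mo0 = 0.064, mt_min = 13, mt_max = 17,
                           lit_A = -1.5, lit_ltsk = 0.350, lit_Fmax = 600),
    sol = muscle_constants("sol", l_OA = 0.260, l_OB = 0.045, phi0 = 0.44,
                           l_mo0 = 0.055, mt_min = 14, mt_max = 19,
                           lit_A = -1.5, lit_ltsk = 0.228, lit_Fmax = 2800)
  )
}

#' Normalized muscle-curve constants
#'
#' Shape constants of the generic Hill-type curves. The active force-length
#' curve is a Gaussian in normalized fascicle length, `exp(-(l-1)^2 / width)`;
#' the force-velocity curve is hyperbolic for shortening with an exponential
#' eccentric branch rising to `fv_ecc_max` (slope-matched at zero velocity);
#' the passive curve is exponential above optimal length.
#'
#' @param fl_width width of the Gaussian force-length curve (default 0.45).
#' @param fv_shape Hill shape parameter of the shortening branch (default
#'   0.25).
#' @param fv_ecc_max eccentric force plateau, multiples of maximal isometric
#'   force (default 1.4).
#' @param fp_exp,fp_width exponent and strain scale of the passive curve
#'   (defaults 4 and 0.6).
#' @return A named list of curve constants.
#' @export
muscle_curves <- function(fl_width = 0.45, fv_shape = 0.25, fv_ecc_max = 1.4,
                          fp_exp = 4, fp_width = 0.6) {
  list(fl_width = fl_width, fv_shape = fv_shape, fv_ecc_max = fv_ecc_max,
       fp_exp = fp_exp, fp_width = fp_width)
}

#' Musculotendon length from the joint angle
#'
#' Law-of-cosines length of the two-segment path:
#' `l_mt = sqrt(l_OA^2 + l_OB^2 - 2 l_OA l_OB cos(q))`.
#'
#' @param q included angle between the two segments in rad, in (0, pi).
#'   Vectorized.
#' @param constants a [muscle_constants()] object.
#' @return Length(s) in m.
#' @export
mtu_length <- function(q, constants) {
  sqrt(constants$l_OA^2 + constants$l_OB^2 -
         2 * constants$l_OA * constants$l_OB * cos(q))
}

#' Musculotendon moment arm
#'
#' Under the default `"derivative"` convention the moment arm is the exact
#' partial derivative of [mtu_length()] with respect to the joint angle,
#' `r = l_OA l_OB sin(q) / l_mt`. The `"printed"` convention returns twice
#' that value, reproducing the commonly typeset law-of-sines form
#' `2 l_OA l_OB sin(q) / l_mt`; the derivative convention is internally
#' consistent with the geometry and is the package default.
#'
#' @inheritParams mtu_length
#' @param convention `"derivative"` (default) or `"printed"`.
#' @return Moment arm(s) in m.
#' @export
moment_arm <- function(q, constants, convention = c("derivative", "printed")) {
  convention <- match.arg(convention)
  r <- constants$l_OA * constants$l_OB * sin(q) / mtu_length(q, constants)
  if (convention == "printed") 2 * r else r
}

#' Activation-dependent optimal fascicle length
#'
#' `l_m0(a) = l_mo0 * (lambda * (1 - a) + 1)`: the optimal fascicle length
#' increases as activation decreases, at rate `lambda` (default 0.15).
#'
#' @param a activation in \[0, 1\] (vectorized).
#' @param constants a [muscle_constants()] object.
#' @return Optimal fascicle length(s) in m, decreasing in `a`.
#' @export
optimal_fascicle_length <- function(a, constants) {
  if (any(a < -1e-9) || any(a > 1 + 1e-9))
    stop("data error: activation must lie in [0, 1]", call. = FALSE)
  constants$l_mo0 * (constants$lambda * (1 - a) + 1)
}

#' Pennation angle at a given fascicle length
#'
#' Constant-thickness assumption: the muscle belly keeps
#' `l_m sin(phi) = l_m0 sin(phi0)`, so `phi = asin(l_m0 sin(phi0) / l_m)`.
#' If the fascicle is shorter than the constant thickness the argument is
#' clamped to 1 (degenerate, logged as a warning).
#'
#' @param l_m fascicle length in m (vectorized).
#' @param l_m0 optimal fascicle length in m.
#' @param phi0 optimal pennation angle in rad.
#' @return Pennation angle(s) in rad.
#' @export
pennation <- function(l_m, l_m0, phi0) {
  arg <- l_m0 * sin(phi0) / l_m
  if (any(arg > 1)) {
    warning("pennation: arcsin argument > 1 clamped (degenerate short fascicle)",
            call. = FALSE)
    arg <- pmin(arg, 1)
  }
  asin(arg)
}

#' Piecewise tendon force-strain law
#'
#' Nominal tendon force as a function of tendon strain
#' `xi = (l_t - ltsk) / ltsk`: zero when slack, quadratic toe region
#' `1480.3 Fmax xi^2` for `0 < xi < 0.0127`, linear region
#' `(37.5 xi - 0.2375) Fmax` beyond. The two branches agree at the junction to
#' better than 1e-4 relative and the slopes differ by about 0.3\%.
#'
#' @param xi tendon strain (dimensionless, vectorized).
#' @param Fmax maximal contraction force in N.
#' @return Tendon force(s) in N, nonnegative and nondecreasing in `xi`.
#' @export
tendon_force <- function(xi, Fmax) {
  if (Fmax <= 0) stop("config error: Fmax must be positive", call. = FALSE)
  ifelse(xi <= 0, 0,
         ifelse(xi < 0.0127, 1480.3 * Fmax * xi^2,
                (37.5 * xi - 0.2375) * Fmax))
}

#' Normalized Hill-type muscle curves
#'
#' Active force-length `force_length()`, force-velocity `force_velocity()` and
#' passive force `passive_force()` curves, all normalized: `f_l(1) = 1`,
#' `f_v(0) = 1`, `f_v(-1) = 0` (maximal shortening), `f_p(l) = 0` for
#' `l <= 1`.
#'
#' @param l_tilde fascicle length normalized to the (activation-dependent)
#'   optimal length.
#' @param v_tilde fascicle velocity normalized to `v_max` (negative =
#'   shortening).
#' @param curves a [muscle_curves()] list.
#' @return Dimensionless force scaling factor(s).
#' @name muscle_curve_fns
NULL

#' @rdname muscle_curve_fns
#' @export
force_length <- function(l_tilde, curves = muscle_curves()) {
  exp(-(l_tilde - 1)^2 / curves$fl_width)
}

#' @rdname muscle_curve_fns
#' @export
force_velocity <- function(v_tilde, curves = muscle_curves()) {
  k <- curves$fv_shape
  fve <- curves$fv_ecc_max
  kecc <- (fve - 1) * k / (k + 1)
  ifelse(v_tilde <= -1, 0,
         ifelse(v_tilde <= 0, (1 + v_tilde) / (1 - v_tilde / k),
                fve - (fve - 1) * exp(-v_tilde / kecc)))
}

#' @rdname muscle_curve_fns
#' @export
passive_force <- function(l_tilde, curves = muscle_curves()) {
  ifelse(l_tilde <= 1, 0,
         (exp(curves$fp_exp * (l_tilde - 1) / curves$fp_width) - 1) /
           (exp(curves$fp_exp) - 1))
}

#' Musculotendon contraction force
#'
#' Hill-type force of the contractile and passive elements projected on the
#' tendon line of action:
#' `F_mt = (Fmax f_l f_v a + Fmax f_p) cos(phi)`.
#'
#' @param l_m fascicle length in m.
#' @param v_m fascicle velocity in m/s (negative = shortening).
#' @param a activation in \[0, 1\].
#' @param phi pennation angle in rad.
#' @param constants a [muscle_constants()] object.
#' @param Fmax maximal contraction force in N.
#' @param curves a [muscle_curves()] list.
#' @return Force in N (nonnegative).
#' @export
muscle_force <- function(l_m, v_m, a, phi, constants, Fmax,
                         curves = muscle_curves()) {
  l_m0 <- optimal_fascicle_length(a, constants)
  lt <- l_m / l_m0
  Fmax * (force_length(lt, curves) * force_velocity(v_m / constants$v_max,
                                                    curves) * a +
            passive_force(lt, curves)) * cos(phi)
}

#' Solve the tendon-muscle equilibrium at one sample
#'
#' Finds the tendon length `l_t` at which the tendon force balances the
#' fascicle force for a given musculotendon length and activation. The
#' fascicle geometry follows the constant-thickness pennation assumption, so
#' `l_m = sqrt((l_mt - l_t)^2 + h^2)` with `h = l_m0 sin(phi0)`, and the
#' fascicle velocity is the backward difference against the previous solved
#' state (zero at the first sample). The root is bracketed between a slack
#' tendon and `l_t = l_mt` and solved to a force residual below
#' `1e-6 * Fmax`; if no force is transmitted the slack solution
#' `l_t = min(l_mt, ltsk)` is returned.
#'
#' @param l_mt musculotendon length in m.
#' @param a activation in \[0, 1\].
#' @param prev previous `muscle_state` (or `NULL` at the first sample).
#' @param constants a [muscle_constants()] object.
#' @param ltsk tendon slack length in m.
#' @param Fmax maximal contraction force in N.
#' @param dt sample interval in s.
#' @param curves a [muscle_curves()] list.
#' @param tendon_scale multiplier on tendon stiffness (1 = nominal; large
#'   values approach a rigid tendon).
#' @return An object of class `muscle_state`: list with `l_mt`, `l_t`, `xi`,
#'   `l_m`, `phi`, `v_m`, `F_mt`, `resid`.
#' @export
solve_equilibrium <- function(l_mt, a, prev = NULL, constants, ltsk, Fmax,
                              dt = 0.01, curves = muscle_curves(),
                              tendon_scale = 1) {
  if (l_mt <= 0.5 * ltsk)
    stop("data error: l_mt implausibly short relative to tendon slack length",
         call. = FALSE)
  l_m0 <- optimal_fascicle_length(a, constants)
  h <- l_m0 * sin(constants$phi0)
  lm_prev <- if (is.null(prev)) NULL else prev$l_m

  state_at <- function(l_t) {
    w <- max(l_mt - l_t, 0)
    l_m <- sqrt(w^2 + h^2)
    phi <- atan2(h, w)
    v_m <- if (is.null(lm_prev)) 0 else (l_m - lm_prev) / dt
    F_mt <- muscle_force(l_m, v_m, a, phi, constants, Fmax, curves)
    list(l_m = l_m, phi = phi, v_m = v_m, F_mt = F_mt)
  }
  g <- function(l_t) {
    tendon_scale * tendon_force((l_t - ltsk) / ltsk, Fmax) - state_at(l_t)$F_mt
  }

  lt_slack <- min(ltsk, l_mt)
  if (state_at(lt_slack)$F_mt <= 1e-9 * Fmax) {
    l_t <- lt_slack
  } else {
    lo <- min(0.9 * ltsk, l_mt)
    root <- stats::uniroot(g, c(lo, l_mt), tol = 1e-14)
    l_t <- root$root
  }
  st <- state_at(l_t)
  xi <- (l_t - ltsk) / ltsk
  structure(list(l_mt = l_mt, l_t = l_t, xi = xi, l_m = st$l_m, phi = st$phi,
                 v_m = st$v_m, F_mt = st$F_mt,
                 resid = tendon_scale * tendon_force(xi, Fmax) - st$F_mt),
            class = "muscle_state")
}

#' Solve the equilibrium along a whole trajectory
#'
#' Sequential per-sample equilibrium solve (compiled kernel) for one muscle:
#' given musculotendon length and activation trajectories on a uniform grid,
#' returns the solved state at every sample.
#'
#' @param l_mt numeric vector of musculotendon lengths in m.
#' @param a numeric vector of activations in \[0, 1\] (same length).
#' @param constants a [muscle_constants()] object.
#' @param ltsk tendon slack length in m.
#' @param Fmax maximal contraction force in N.
#' @param dt sample interval in s.
#' @param curves a [muscle_curves()] list.
#' @param tendon_scale tendon stiffness multiplier (default 1).
#' @return A data frame with columns `l_t`, `xi`, `l_m`, `phi`, `v_m`,
#'   `F_mt`, `resid`, one row per sample.
#' @export
muscle_forward <- function(l_mt, a, constants, ltsk, Fmax, dt,
                           curves = muscle_curves(), tendon_scale = 1) {
  pars <- c(ltsk = ltsk, Fmax = Fmax, lmo0 = constants$l_mo0,
            phi0 = constants$phi0, lambda = constants$lambda,
            vmax = constants$v_max, fl_width = curves$fl_width,
            fv_shape = curves$fv_shape, fv_ecc_max = curves$fv_ecc_max,
            fp_exp = curves$fp_exp, fp_width = curves$fp_width,
            tendon_scale = tendon_scale)
  m <- .muscle_forward_cpp(as.numeric(l_mt), as.numeric(a), dt, pars)
  as.data.frame(m)
}

#' Net joint moment from per-muscle states
#'
#' Per-sample net plantarflexion moment `sum_i F_mt_i * r_mt_i` over the
#' modelled muscles.
#'
#' @param states list of per-muscle state data frames (from
#'   [muscle_forward()]), all on the same grid.
#' @param moment_arms list of per-muscle moment-arm vectors (m), matching
#'   `states`.
#' @return Numeric vector of net moments in N m.
#' @export
joint_moment <- function(states, moment_arms) {
  stopifnot(length(states) == length(moment_arms))
  n <- unique(c(vapply(states, nrow, 1L),
                vapply(moment_arms, length, 1L)))
  if (length(n) != 1L)
    stop("alignment error: per-muscle states on different grids", call. = FALSE)
  out <- numeric(n)
  for (i in seq_along(states)) out <- out + states[[i]]$F_mt * moment_arms[[i]]
  out
}
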