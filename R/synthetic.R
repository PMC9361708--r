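#' Configuration of the synthetic gait-trial generator
#'
#' Defines the study conditions the generator emulates: five treadmill speeds
#' from 0.50 to 1.50 m/s, stance-phase plantarflexor bursts whose magnitude
#' grows with speed, muscle-thickness traces bounded by subject-constant
#' rest/MVC values, sEMG envelopes normalized to a cross-speed task peak, and
#' a benchmark moment produced by the forward model itself under known
#' parameters. The noise model gives each sensing modality a distinct failure
#' mode: short multiplicative bursts on the sEMG envelope (cross-talk
#' analogue), slow additive drift on muscle thickness (tracking-error
#' accumulation analogue), and white noise on the benchmark moment.
#'
#' @param speeds treadmill speeds in m/s.
#' @param n_cycles gait cycles generated per speed (default 16, roughly a
#'   20 s record at comfortable speed).
#' @param fs_model model grid rate in Hz.
#' @param body_mass subject body mass in kg (default 78.0).
#' @param true_params generating [hnm_parameters()]; defaults lie inside the
#'   calibration box.
#' @param semg_burst_sd amplitude SD of the multiplicative sEMG bursts
#'   (default 0.3; 0 disables).
#' @param mt_drift_rate SD of the linear muscle-thickness drift slope in mm/s
#'   (default 0.05; 0 disables).
#' @param moment_sd white-noise SD on the benchmark moment in N m
#'   (default 2; 0 disables).
#' @param seed integer seed fixing all randomness.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(speeds = c(0.50, 0.75, 1.00, 1.25, 1.50),
                             n_cycles = 16, fs_model = 100, body_mass = 78.0,
                             true_params = NULL,
                             semg_burst_sd = 0.3, mt_drift_rate = 0.05,
                             moment_sd = 2, seed = 1) {
  if (any(speeds <= 0)) stop("config error: speeds must be positive",
                             call. = FALSE)
  if (is.null(true_params))
    true_params <- hnm_parameters(
      lgs = list(A = -2.0, ltsk = 0.355, Fmax = 650, delta = 0.60),
      sol = list(A = -1.2, ltsk = 0.234, Fmax = 3100, delta = 0.50))
  structure(list(speeds = speeds, n_cycles = n_cycles, fs_model = fs_model,
                 body_mass = body_mass, true_params = true_params,
                 semg_burst_sd = semg_burst_sd, mt_drift_rate = mt_drift_rate,
                 moment_sd = moment_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

# shared gait timing: stride shortens and stance fraction shrinks with speed
.gait_timing <- function(speed) {
  list(stride = 2.0 - 0.6 * speed,
       stance_frac = 0.66 - 0.04 * (speed - 0.5))
}

# phase grid for n_cycles strides with 0.5 s quiet lead-in and lead-out;
# phase is NA outside the strides
.gait_phase <- function(speed, n_cycles, fs) {
  tm <- .gait_timing(speed)
  lead <- round(0.5 * fs)
  nper <- round(tm$stride * fs)
  n <- 2 * lead + n_cycles * nper
  phase <- rep(NA_real_, n)
  if (n_cycles > 0) {
    k <- seq_len(n_cycles * nper) - 1
    phase[lead + seq_len(n_cycles * nper)] <- (k %% nper) / nper
  }
  cyc <- rep(NA_integer_, n)
  if (n_cycles > 0)
    cyc[lead + seq_len(n_cycles * nper)] <-
      rep(seq_len(n_cycles), each = nper)
  list(n = n, phase = phase, cycle = cyc, stance_frac = tm$stance_frac,
       nper = nper, lead = lead)
}

# smooth raised-cosine bump centred at c with half-width w, on [0,1]
.bump <- function(s, centre, width) {
  ifelse(abs(s - centre) < width,
         0.5 * (1 + cos(pi * (s - centre) / width)), 0)
}

#' Synthetic ankle kinematics and ground reaction force
#'
#' Generates a periodic anatomical ankle-angle trajectory (early
#' plantarflexion dip, dorsiflexion ramp, push-off plantarflexion) and a
#' smooth double-hump vertical GRF for one speed. Stance duration and
#' fraction decrease with speed; cycle-to-cycle amplitude jitter is seeded.
#'
#' @param speed treadmill speed in m/s.
#' @param n_cycles number of gait cycles (0 gives empty vectors).
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param body_mass body mass in kg (scales the GRF).
#' @return A list with numeric vectors `theta` (rad, dorsiflexion positive)
#'   and `grf` (N), plus `fs` and the stance fraction used.
#' @export
make_kinematics <- function(speed, n_cycles, fs, seed, body_mass = 78.0) {
  if (n_cycles == 0)
    return(list(theta = numeric(0), grf = numeric(0), fs = fs,
                stance_frac = .gait_timing(speed)$stance_frac))
  ph <- .gait_phase(speed, n_cycles, fs)
  .with_seed(seed, {
    amp_jit <- stats::rnorm(n_cycles, 1, 0.02)
    th_max <- 0.18 + 0.04 * speed
    th_min <- -(0.20 + 0.10 * speed)
    sf <- ph$stance_frac
    # periodic spline through key postures over one cycle
    kn_p <- c(0, 0.10 * sf, 0.45 * sf, 0.75 * sf, sf, sf + 0.10,
              sf + 0.55 * (1 - sf), 1)
    kn_v <- c(0, -0.08, 0.6 * th_max, th_max, 0.5 * th_min, th_min, 0.04, 0)
    base <- stats::spline(kn_p, kn_v, method = "periodic",
                          xout = ((seq_len(ph$nper) - 1) / ph$nper))$y
    theta <- rep(0, ph$n)
    grf <- rep(0, ph$n)
    bw <- body_mass * 9.81
    amp_g <- 1.00 + 0.10 * speed
    for (c in seq_len(n_cycles)) {
      sel <- which(!is.na(ph$cycle) & ph$cycle == c)
      theta[sel] <- base * amp_jit[c]
      s <- ph$phase[sel] / sf
      in_st <- s < 1
      g <- pmax(sin(pi * s) + 0.2 * sin(3 * pi * s), 0)
      grf[sel[in_st]] <- bw * amp_g * amp_jit[c] * g[in_st]
    }
    list(theta = theta, grf = grf, fs = fs, stance_frac = sf)
  })
}

#' Synthetic stance-phase activation bursts
#'
#' Smooth unimodal bursts of normalized sEMG envelope (`u`) and
#' ultrasound-derived activation (`a2`) over each stance phase, near zero in
#' swing. Peak amplitude increases with walking speed; the sEMG and
#' ultrasound components have deliberately different timing and width so the
#' allocation gain is identifiable. Cycle-to-cycle peak jitter is seeded.
#'
#' @inheritParams make_kinematics
#' @return A list with numeric vectors `u_lgs`, `u_sol`, `a2_lgs`, `a2_sol`,
#'   all in \[0, 1\].
#' @export
make_activations <- function(speed, n_cycles, fs, seed) {
  if (n_cycles == 0)
    return(list(u_lgs = numeric(0), u_sol = numeric(0),
                a2_lgs = numeric(0), a2_sol = numeric(0)))
  ph <- .gait_phase(speed, n_cycles, fs)
  shapes <- list(
    u_lgs = list(centre = 0.72, width = 0.32, peak = 0.30 + 0.42 * speed,
                 base = 0.02),
    u_sol = list(centre = 0.66, width = 0.36, peak = 0.33 + 0.40 * speed,
                 base = 0.02),
    a2_lgs = list(centre = 0.60, width = 0.45, peak = 0.35 + 0.38 * speed,
                  base = 0.05),
    a2_sol = list(centre = 0.56, width = 0.50, peak = 0.38 + 0.36 * speed,
                  base = 0.05))
  .with_seed(seed, {
    jit <- matrix(stats::rnorm(4 * n_cycles, 1, 0.03), nrow = 4)
    out <- lapply(seq_along(shapes), function(j) {
      sh <- shapes[[j]]
      x <- rep(sh$base, ph$n)
      for (c in seq_len(n_cycles)) {
        sel <- which(!is.na(ph$cycle) & ph$cycle == c)
        s <- ph$phase[sel] / ph$stance_frac
        x[sel] <- sh$base +
          sh$peak * jit[j, c] * .bump(pmin(s, 1.5), sh$centre, sh$width)
      }
      .clip01(x)
    })
    names(out) <- names(shapes)
    out
  })
}

# short multiplicative burst noise on an envelope (cross-talk analogue)
.burst_noise <- function(n, fs, sd, seed) {
  if (sd <= 0) return(rep(1, n))
  .with_seed(seed, {
    dur <- n / fs
    k <- stats::rpois(1, 0.7 * dur)    # about 0.7 bursts per second
    f <- rep(1, n)
    if (k > 0) {
      centres <- stats::runif(k, 0, dur)
      amps <- stats::rnorm(k, 0, sd)
      t <- (seq_len(n) - 1) / fs
      for (j in seq_len(k))
        f <- f + amps[j] * .bump(t, centres[j], 0.05)
    }
    pmax(f, 0)
  })
}

#' Generate a full set of synthetic gait trials
#'
#' Builds one trial per speed with internally consistent channels: the
#' benchmark moment channel is the forward model's own output under the
#' configured true parameters, the sEMG channel is the normalized envelope
#' (cross-speed maximum scaled to exactly 1, i.e. the task-peak normalization
#' holds by construction) corrupted by multiplicative bursts, and the
#' muscle-thickness channel is the exact inverse of the activation
#' normalization plus a slow seeded drift. With all noise terms zero the
#' channels are exactly consistent with the generating model.
#'
#' @param config a [synthetic_config()] object.
#' @param constants per-muscle constants, as [default_muscle_constants()].
#' @param control an [hnm_control()] list.
#' @return A list of [gait_trial] objects (one per speed) with the generator
#'   truth attached as attribute `"truth"` (per speed: clean `u`, `a2`,
#'   fused activations and clean moment) and the configuration as
#'   `"config"`.
#' @export
forward_generate <- function(config = synthetic_config(),
                             constants = default_muscle_constants(),
                             control = hnm_control()) {
  fs <- config$fs_model
  base_seed <- as.integer(config$seed %% 1000000L)
  sub_seed <- function(j, role) base_seed * 1000L + j * 10L + role

  kin <- list(); act <- list()
  for (j in seq_along(config$speeds)) {
    sp <- config$speeds[j]
    kin[[j]] <- make_kinematics(sp, config$n_cycles, fs, sub_seed(j, 1),
                                body_mass = config$body_mass)
    act[[j]] <- make_activations(sp, config$n_cycles, fs, sub_seed(j, 2))
  }
  # task-peak normalization across speeds, per muscle: each muscle's
  # cross-speed envelope maximum is exactly 1
  for (ch in c("u_lgs", "u_sol")) {
    gmax <- max(vapply(act, function(a) max(a[[ch]]), 1))
    for (j in seq_along(act)) act[[j]][[ch]] <- act[[j]][[ch]] / gmax
  }

  trials <- list(); truth <- list()
  for (j in seq_along(config$speeds)) {
    sp <- config$speeds[j]
    n <- length(kin[[j]]$theta)
    fw <- hnm_forward(kin[[j]]$theta, act[[j]]$u_lgs, act[[j]]$u_sol,
                      act[[j]]$a2_lgs, act[[j]]$a2_sol, config$true_params,
                      constants, control, fs = fs)
    semg <- list()
    for (m in c("lgs", "sol")) {
      u <- act[[j]][[paste0("u_", m)]]
      semg[[m]] <- u * .burst_noise(n, fs, config$semg_burst_sd,
                                    sub_seed(j, if (m == "lgs") 3L else 4L))
    }
    mt <- list()
    for (m in c("lgs", "sol")) {
      cst <- constants[[m]]
      a2 <- act[[j]][[paste0("a2_", m)]]
      drift <- if (config$mt_drift_rate > 0)
        .with_seed(sub_seed(j, if (m == "lgs") 5L else 6L),
                   stats::rnorm(1, 0, config$mt_drift_rate)) * (seq_len(n) - 1) / fs
      else 0
      mt[[m]] <- cst$mt_min + a2 * (cst$mt_max - cst$mt_min) + drift
    }
    moment <- fw$moment
    if (config$moment_sd > 0)
      moment <- moment + .with_seed(sub_seed(j, 7L),
                                    stats::rnorm(n, 0, config$moment_sd))

    mk <- function(v, units) uniform_series(v, fs = fs, units = units)
    trials[[j]] <- gait_trial(
      channels = list(angle = mk(kin[[j]]$theta, "rad"),
                      grf = mk(kin[[j]]$grf, "N"),
                      semg_lgs = mk(semg$lgs, ""),
                      semg_sol = mk(semg$sol, ""),
                      mt_lgs = mk(mt$lgs, "mm"),
                      mt_sol = mk(mt$sol, "mm"),
                      moment = mk(moment, "N.m")),
      speed = sp, body_mass = config$body_mass,
      semg_is_envelope = TRUE, mt_is_filtered = TRUE,
      id = sprintf("synth_%04.2fms", sp))
    truth[[j]] <- list(speed = sp, u_lgs = act[[j]]$u_lgs,
                       u_sol = act[[j]]$u_sol, a2_lgs = act[[j]]$a2_lgs,
                       a2_sol = act[[j]]$a2_sol,
                       a = fw$a, moment = fw$moment)
  }
  attr(trials, "truth") <- truth
  attr(trials, "config") <- config
  trials
}

#' Synthesize a raw sEMG record from an envelope
#'
#' Emulates an analog-rate raw sEMG channel by amplitude-modulating
#' band-limited noise with an envelope profile; used to exercise the
#' band-pass/rectify/low-pass envelope pipeline against a known modulation.
#'
#' @param u envelope profile in \[0, 1\] on the model grid.
#' @param fs_model model grid rate in Hz.
#' @param fs_out analog output rate in Hz (default 1000).
#' @param seed integer seed.
#' @return Numeric vector of raw sEMG samples at `fs_out`.
#' @export
synthesize_raw_semg <- function(u, fs_model = 100, fs_out = 1000, seed = 1) {
  env <- pmax(resample_series(.series_values(u), fs_out, fs = fs_model), 0)
  n <- length(env)
  .with_seed(seed, {
    carrier <- stats::rnorm(n)
    bp <- .butter_coeffs(4, c(20, 450), fs_out, "pass")
    carrier <- .zerophase_filter(bp$b, bp$a, carrier)
    carrier <- carrier / stats::sd(carrier)
    env * carrier
  })
}
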