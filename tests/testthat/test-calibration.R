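test_that("dataset assembly: cycle counts, disjointness, determinism", {
  pt <- fx_trials(seed = 11, n_cycles = 8)
  ds <- build_calibration_dataset(pt, mode = "inter", seed = 3)
  expect_equal(nrow(ds$calib), 10)
  expect_equal(as.vector(table(ds$calib$speed)), rep(2, 5))
  # held-out cycles disjoint from calibration cycles
  key <- function(d) paste(d$trial, d$heel_strike_idx)
  expect_length(intersect(key(ds$calib), key(ds$holdout)), 0)
  # single-speed mode: all ten cycles from one speed
  pt16 <- fx_trials(seed = 11, n_cycles = 16)
  ds1 <- build_calibration_dataset(pt16, mode = "single", speed = 0.75,
                                   seed = 3)
  expect_equal(nrow(ds1$calib), 10)
  expect_true(all(ds1$calib$speed == 0.75))
  # determinism
  ds2 <- build_calibration_dataset(pt, mode = "inter", seed = 3)
  expect_identical(ds$calib, ds2$calib)
  expect_identical(ds$holdout, ds2$holdout)
  # insufficient cycles
  expect_error(build_calibration_dataset(pt, mode = "single", speed = 0.5,
                                         seed = 1),
               "steady cycles")
})

test_that("objective is the mean squared moment error", {
  pt <- fx_trials(seed = 11, n_cycles = 8)
  ds <- build_calibration_dataset(pt, mode = "inter", seed = 3)
  truth <- fx_true_params()
  # noise-free data generated by the same model: objective ~ 0 at the truth
  expect_lt(hnm_objective(truth, ds), 1e-12)
  # constant offset d on the benchmark shifts the objective to d^2
  ds_off <- ds
  for (j in seq_along(ds_off$trials))
    ds_off$trials[[j]]$proc$moment <- ds_off$trials[[j]]$proc$moment + 2
  expect_equal(hnm_objective(truth, ds_off), 4, tolerance = 1e-6)
})

test_that("variant contracts pin the allocation gain", {
  pt <- fx_trials(seed = 11, n_cycles = 8)
  f_semg <- hnm_fit(pt, mode = "inter", variant = "semg_only", seed = 2)
  expect_identical(f_semg$params$lgs$delta, 1)
  expect_identical(f_semg$params$sol$delta, 1)
  f_us <- hnm_fit(pt, mode = "inter", variant = "us_only", seed = 2)
  expect_identical(f_us$params$lgs$delta, 0)
  expect_identical(f_us$params$sol$delta, 0)
})

test_that("fit respects bounds, descends, and is reproducible", {
  pt <- fx_trials(seed = 12, noise = TRUE, n_cycles = 8)
  fit <- hnm_fit(pt, mode = "inter", variant = "fused", seed = 5)
  for (m in c("lgs", "sol")) {
    b <- fit$bounds[[m]]
    p <- unlist(fit$params[[m]])
    expect_true(all(p >= b$lower - 1e-12 & p <= b$upper + 1e-12))
  }
  expect_lte(fit$objective, fit$start_objective)
  fit2 <- hnm_fit(pt, mode = "inter", variant = "fused", seed = 5)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$objective, fit2$objective)
})

test_that("noise-free calibration recovers the generating parameters", {
  for (s in 1:2) {
    pt <- fx_trials(seed = s, n_cycles = 8)
    fit <- hnm_fit(pt, mode = "inter", variant = "fused", seed = s)
    truth <- fx_true_params()
    for (m in c("lgs", "sol")) {
      expect_lt(abs(fit$params[[m]]$delta - truth[[m]]$delta), 0.05)
      expect_lt(abs(fit$params[[m]]$Fmax - truth[[m]]$Fmax) / truth[[m]]$Fmax,
                0.05)
    }
  }
})

test_that("prediction with the true parameters closes the loop", {
  pt <- fx_trials(seed = 13, n_cycles = 8)
  fit <- hnm_fit(pt, mode = "inter", variant = "fused", seed = 1)
  fit$params <- fx_true_params()   # evaluate the generating parameters
  met <- evaluate_fit(fit)
  expect_true(all(met$r2 >= 0.999))
})

test_that("unimodal predictions ignore the other modality's channel", {
  cfg <- synthetic_config(seed = 21, n_cycles = 8, semg_burst_sd = 0,
                          mt_drift_rate = 0, moment_sd = 0)
  trials <- forward_generate(cfg)
  pt <- prepare_trials(trials)
  f1 <- hnm_fit(pt, mode = "inter", variant = "semg_only", seed = 4)
  p_ref <- predict(f1)
  # scramble the thickness channels and re-prepare: delta = 1 is blind to MT
  scr <- trials
  for (j in seq_along(scr)) {
    for (ch in c("mt_lgs", "mt_sol")) {
      v <- scr[[j]]$channels[[ch]]
      scr[[j]]$channels[[ch]] <- uniform_series(rev(v$values), v$fs,
                                                units = v$units)
    }
  }
  p_scr <- predict(f1, newdata = prepare_trials(scr),
                   cycles = f1$dataset$holdout)
  expect_equal(p_ref$pred, p_scr$pred, tolerance = 1e-12)
  # delta = 0 is blind to the sEMG channel
  f0 <- hnm_fit(pt, mode = "inter", variant = "us_only", seed = 4)
  p0_ref <- predict(f0)
  scr2 <- trials
  for (j in seq_along(scr2)) {
    for (ch in c("semg_lgs", "semg_sol")) {
      v <- scr2[[j]]$channels[[ch]]
      scr2[[j]]$channels[[ch]] <- uniform_series(rev(v$values), v$fs,
                                                 units = v$units)
    }
  }
  p0_scr <- predict(f0, newdata = prepare_trials(scr2),
                    cycles = f0$dataset$holdout)
  expect_equal(p0_ref$pred, p0_scr$pred, tolerance = 1e-12)
})

test_that("recovery degrades gracefully with benchmark noise", {
  seeds <- 1:10
  err <- sapply(c(0, 2, 5), function(sd_m) {
    mean(sapply(seeds, function(s) {
      cfg <- synthetic_config(seed = 100 + s, n_cycles = 8,
                              semg_burst_sd = 0, mt_drift_rate = 0,
                              moment_sd = sd_m)
      pt <- prepare_trials(forward_generate(cfg))
      fit <- hnm_fit(pt, mode = "inter", variant = "fused", seed = s)
      truth <- fx_true_params()
      mean(c(abs(fit$params$lgs$delta - truth$lgs$delta),
             abs(fit$params$sol$delta - truth$sol$delta)))
    }))
  })
  expect_true(all(diff(err) >= -1e-9))
})
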