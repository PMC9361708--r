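test_that("generation is fully determined by the seed", {
  cfg <- synthetic_config(seed = 5, n_cycles = 4)
  t1 <- forward_generate(cfg)
  t2 <- forward_generate(cfg)
  for (j in seq_along(t1))
    for (ch in names(t1[[j]]$channels))
      expect_identical(t1[[j]]$channels[[ch]]$values,
                       t2[[j]]$channels[[ch]]$values)
  t3 <- forward_generate(synthetic_config(seed = 6, n_cycles = 4))
  expect_false(identical(t1[[1]]$channels$moment$values,
                         t3[[1]]$channels$moment$values))
})

test_that("kinematics: empty case, determinism, stance structure", {
  k0 <- make_kinematics(1.0, 0, 100, seed = 1)
  expect_length(k0$theta, 0)
  k1 <- make_kinematics(1.0, 5, 100, seed = 1)
  expect_identical(k1, make_kinematics(1.0, 5, 100, seed = 1))
  st <- segment_stance(k1$grf, fs = 100)
  expect_equal(nrow(st), 5)
  # stance duration shrinks with speed
  d_slow <- segment_stance(make_kinematics(0.5, 5, 100, 1)$grf,
                           fs = 100)$duration_s
  d_fast <- segment_stance(make_kinematics(1.5, 5, 100, 1)$grf,
                           fs = 100)$duration_s
  expect_gt(mean(d_slow), mean(d_fast))
})

test_that("activation bursts are bounded, stance-locked and speed-scaled", {
  a <- make_activations(1.0, 6, 100, seed = 2)
  for (x in a) expect_true(all(x >= 0 & x <= 1))
  # quiet outside the strides (small constructed baseline)
  expect_lt(max(a$u_lgs[1:40]), 0.05)
  expect_gt(max(make_activations(1.5, 6, 100, 2)$u_lgs),
            max(make_activations(0.5, 6, 100, 2)$u_lgs))
})

test_that("zero-noise channels are exactly consistent with the model", {
  pt <- fx_trials(seed = 11, n_cycles = 8)
  truth <- attr(pt, "truth")
  cst <- default_muscle_constants()
  for (j in seq_along(pt)) {
    proc <- pt[[j]]$proc
    expect_lt(max(abs(proc$a2_lgs - truth[[j]]$a2_lgs)), 1e-9)
    expect_lt(max(abs(proc$a2_sol - truth[[j]]$a2_sol)), 1e-9)
    expect_lt(max(abs(proc$u_lgs - truth[[j]]$u_lgs)), 1e-9)
    expect_identical(proc$moment, truth[[j]]$moment)
  }
})

test_that("generated peak moment is nondecreasing in speed", {
  pt <- fx_trials(seed = 11, n_cycles = 8)
  peaks <- vapply(pt, function(tr) max(tr$proc$moment), 1)
  expect_true(all(diff(peaks) >= 0))
})

test_that("noise knobs act on their own channel only", {
  base <- forward_generate(synthetic_config(seed = 9, n_cycles = 4,
                                            semg_burst_sd = 0,
                                            mt_drift_rate = 0, moment_sd = 0))
  noisy <- forward_generate(synthetic_config(seed = 9, n_cycles = 4,
                                             semg_burst_sd = 0.5,
                                             mt_drift_rate = 0, moment_sd = 0))
  expect_identical(base[[1]]$channels$mt_lgs$values,
                   noisy[[1]]$channels$mt_lgs$values)
  expect_identical(base[[1]]$channels$moment$values,
                   noisy[[1]]$channels$moment$values)
  drift <- forward_generate(synthetic_config(seed = 9, n_cycles = 4,
                                             semg_burst_sd = 0,
                                             mt_drift_rate = 0.1,
                                             moment_sd = 0))
  expect_identical(base[[1]]$channels$semg_lgs$values,
                   drift[[1]]$channels$semg_lgs$values)
  expect_false(identical(base[[1]]$channels$mt_lgs$values,
                         drift[[1]]$channels$mt_lgs$values))
  # drift grows linearly in time
  d <- drift[[1]]$channels$mt_lgs$values - base[[1]]$channels$mt_lgs$values
  expect_equal(d, seq(0, by = d[2] - d[1], length.out = length(d)),
               tolerance = 1e-9)
})

test_that("raw sEMG synthesis carries the envelope through the pipeline", {
  u <- make_activations(1.0, 6, 100, seed = 3)$u_lgs
  raw <- synthesize_raw_semg(u, fs_model = 100, fs_out = 1000, seed = 3)
  env <- bandpass_envelope(raw, fs = 1000)
  env100 <- resample_series(env, 100, fs = 1000)
  n <- min(length(env100), length(u))
  expect_gt(stats::cor(env100[1:n], u[1:n]), 0.9)
})
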