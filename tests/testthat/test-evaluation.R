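test_that("metric bundle arithmetic and invariances", {
  truth <- c(10, 20, 30, 25, 15)
  m0 <- hnm_metrics(truth, truth, peak_moment = 100, body_mass = 80)
  expect_equal(unlist(m0[c("rmse", "n_rmse", "bm_rmse", "r2")]),
               c(rmse = 0, n_rmse = 0, bm_rmse = 0, r2 = 1))
  m1 <- hnm_metrics(truth + 10, truth, peak_moment = 100, body_mass = 80)
  expect_equal(m1$rmse, 10)
  expect_equal(m1$n_rmse, 10)
  expect_equal(m1$bm_rmse, 0.125)
  # constant predictor at the truth mean has r2 = 0
  m2 <- hnm_metrics(rep(mean(truth), 5), truth, 100, 80)
  expect_equal(m2$r2, 0)
  # rmse invariant to a common shift; r2 invariant to a common affine map
  set.seed(6)
  p <- rnorm(50); y <- rnorm(50)
  ma <- hnm_metrics(p, y, 100, 80)
  mb <- hnm_metrics(p + 3, y + 3, 100, 80)
  expect_equal(ma$rmse, mb$rmse)
  mc <- hnm_metrics(2 * p + 1, 2 * y + 1, 100, 80)
  expect_equal(ma$r2, mc$r2)
  expect_error(hnm_metrics(p, rep(1, 50), 100, 80), "zero-variance")
  expect_error(hnm_metrics(p, y[1:10], 100, 80), "alignment")
  expect_error(hnm_metrics(p, y, -1, 80), "config error")
})

# build a minimal processed trial whose features have known relationships to
# the benchmark moment
.toy_trial <- function(n_cycles, feature_maker, seed = 1) {
  fs <- 100
  set.seed(seed)
  per <- fs               # 1 s cycles: 0.6 s stance, 0.4 s swing
  n <- n_cycles * per + 2 * fs
  stance <- rep(FALSE, n)
  mom <- numeric(n)
  for (c in seq_len(n_cycles)) {
    i0 <- fs + (c - 1) * per
    s <- seq(0, 1, length.out = 60)
    stance[i0 + 1:60] <- TRUE
    mom[i0 + 1:60] <- 80 * sin(pi * s)^2
  }
  grf <- ifelse(stance, 700, 0)
  feats <- feature_maker(mom, stance, n)
  mk <- function(v, u = "") uniform_series(v, fs, units = u)
  tr <- gait_trial(list(angle = mk(rep(0.1, n), "rad"), grf = mk(grf, "N"),
                        semg_lgs = mk(feats$semg, ""),
                        semg_sol = mk(feats$semg, ""),
                        mt_lgs = mk(feats$mt, "mm"),
                        mt_sol = mk(feats$mt, "mm"),
                        moment = mk(mom, "N.m")),
                   speed = 1.0, body_mass = 78,
                   semg_is_envelope = TRUE, mt_is_filtered = TRUE)
  prepare_trials(list(tr))
}

test_that("features proportional to the moment correlate near 1", {
  pt <- .toy_trial(6, function(mom, stance, n) {
    list(semg = mom / max(mom), mt = 14 + 3 * mom / max(mom))
  })
  tab <- correlation_table(pt)
  expect_true(all(tab$mean_r > 0.999))
  expect_true(all(tab$mean_r < 1))
  expect_true(all(tab$n_cycles == 6))
})

test_that("independent noise features aggregate to near-zero correlation", {
  pt <- .toy_trial(50, function(mom, stance, n) {
    list(semg = runif(n), mt = runif(n, 14, 17))
  }, seed = 99)
  tab <- correlation_table(pt)
  expect_true(all(abs(tab$mean_r) < 0.1))
  expect_true(all(tab$mean_r > -1 & tab$mean_r < 1))
})

test_that("variant comparison reports means, percent changes and spread", {
  grid <- expand.grid(variant = c("fused", "semg_only", "us_only"),
                      mode = c("inter", "single_0.50"),
                      speed = c(0.5, 1.0, 1.5), stringsAsFactors = FALSE)
  grid$rmse <- 8; grid$n_rmse <- 10; grid$bm_rmse <- 0.1; grid$r2 <- 0.9
  eq <- compare_variants(grid)
  expect_true(all(abs(eq$by_variant$pct_vs_semg) < 1e-12))
  expect_true(all(eq$spread$across_speed_sd == 0))
  # fused at half the unimodal error shows as -50%
  grid$n_rmse[grid$variant == "fused"] <- 5
  cmp <- compare_variants(grid)
  expect_equal(cmp$by_variant$pct_vs_semg[cmp$by_variant$variant == "fused"],
               -50)
})

test_that("fit summary and simulate methods are coherent", {
  pt <- fx_trials(seed = 12, noise = TRUE, n_cycles = 8)
  fit <- hnm_fit(pt, mode = "inter", variant = "fused", seed = 5)
  s <- summary(fit)
  expect_equal(s$calib_rmse, sqrt(mean(residuals(fit)^2)))
  expect_equal(length(fitted(fit)), s$n_calib_samples)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(s$n_calib_samples, 3))
  sims2 <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(sims, sims2)
})
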