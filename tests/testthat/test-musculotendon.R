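cst_test <- muscle_constants("test", l_OA = 0.40, l_OB = 0.06, phi0 = 0.14,
                             l_mo0 = 0.064, mt_min = 13, mt_max = 17,
                             lit_ltsk = 0.35, lit_Fmax = 600)

test_that("mtu_length follows the law of cosines", {
  expect_equal(mtu_length(pi / 2, cst_test), sqrt(0.40^2 + 0.06^2))
  expect_equal(mtu_length(1e-9, cst_test), 0.40 - 0.06, tolerance = 1e-6)
  # frozen from direct evaluation of the formula
  expect_equal(mtu_length(1.9, cst_test), 0.4232232, tolerance = 1e-6)
})

test_that("moment arm matches the numeric derivative of the path length", {
  expect_equal(moment_arm(1e-12, cst_test), 0, tolerance = 1e-10)
  expect_equal(moment_arm(pi, cst_test), 0, tolerance = 1e-10)
  q <- seq(0.1, 3.0, length.out = 100)
  h <- 1e-6
  num <- (mtu_length(q + h, cst_test) - mtu_length(q - h, cst_test)) / (2 * h)
  expect_lt(max(abs(moment_arm(q, cst_test) - num)), 1e-8)
  expect_equal(moment_arm(q, cst_test, "printed"),
               2 * moment_arm(q, cst_test, "derivative"))
})

test_that("optimal fascicle length decreases with activation at rate lambda", {
  expect_equal(optimal_fascicle_length(1, cst_test), 0.064)
  expect_equal(optimal_fascicle_length(0, cst_test), 1.15 * 0.064)
  expect_equal(optimal_fascicle_length(0.5, cst_test), 1.075 * 0.064)
})

test_that("pennation keeps the muscle-belly thickness constant", {
  expect_equal(pennation(0.064, 0.064, 0.14), 0.14)
  expect_lt(pennation(10, 0.064, 0.14), 1e-3)
  expect_equal(pennation(2 * 0.05, 0.05, 0.2), 0.0994988, tolerance = 1e-6)
  expect_warning(pennation(0.001, 0.064, 0.5), "clamped")
})

test_that("tendon force-strain law: branches, continuity, monotonicity", {
  Fmax <- 600
  expect_equal(tendon_force(-0.01, Fmax), 0)
  expect_equal(tendon_force(0.05, Fmax), 1.6375 * Fmax)
  # branch agreement at the junction strain
  quad <- 1480.3 * Fmax * 0.0127^2
  lin <- (37.5 * 0.0127 - 0.2375) * Fmax
  expect_lt(abs(quad - lin) / lin, 1e-4)
  # slope near-continuity: 2 * 1480.3 * 0.0127 vs 37.5, below 0.5%
  expect_lt(abs(2 * 1480.3 * 0.0127 - 37.5) / 37.5, 0.005)
  xi <- seq(-0.02, 0.1, length.out = 400)
  f <- tendon_force(xi, Fmax)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0))
})

test_that("normalized muscle curves satisfy their conventions", {
  expect_equal(force_length(1), 1)
  expect_equal(force_length(0.8), force_length(1.2))   # Gaussian symmetry
  expect_equal(force_velocity(0), 1)
  expect_equal(force_velocity(-1), 0)
  expect_equal(force_velocity(-2), 0)
  expect_lt(force_velocity(10), muscle_curves()$fv_ecc_max + 1e-9)
  expect_gt(force_velocity(0.05), 1)    # eccentric force above isometric
  expect_equal(passive_force(1), 0)
  expect_equal(passive_force(0.8), 0)
  lt <- seq(1.01, 1.6, by = 0.01)
  expect_true(all(diff(passive_force(lt)) > 0))
})

test_that("muscle force composes the Hill factors", {
  Fmax <- 600
  l0_rest <- optimal_fascicle_length(0, cst_test)
  expect_equal(muscle_force(l0_rest, 0, 0, 0.1, cst_test, Fmax), 0)
  expect_equal(muscle_force(0.064, 0, 1, 0, cst_test, Fmax), Fmax)
  # at max shortening only the passive term survives
  f <- muscle_force(1.2 * 0.064, -cst_test$v_max, 1, 0.2, cst_test, Fmax)
  expect_equal(f, Fmax * passive_force(1.2) * cos(0.2))
})

test_that("equilibrium solve: slack case, construction identity, residual", {
  ltsk <- 0.35; Fmax <- 600
  # inactive muscle, path short enough that passive force vanishes
  s0 <- solve_equilibrium(0.355, 0, NULL, cst_test, ltsk, Fmax)
  expect_identical(s0$l_t, ltsk)
  expect_identical(s0$xi, 0)
  expect_equal(s0$resid, 0)
  for (a in c(0.2, 0.5, 1)) {
    s <- solve_equilibrium(0.41, a, NULL, cst_test, ltsk, Fmax)
    expect_lt(abs(s$l_mt - (s$l_t + s$l_m * cos(s$phi))), 1e-9)
    expect_lt(abs(s$resid), 1e-6 * Fmax)
    # constant-thickness identity, with the activation-dependent optimum
    l_m0 <- optimal_fascicle_length(a, cst_test)
    expect_lt(abs(s$l_m * sin(s$phi) - l_m0 * sin(cst_test$phi0)), 1e-12)
  }
})

test_that("solved tendon strain is monotone in activation (bisection oracle)", {
  ltsk <- 0.35; Fmax <- 600; l_mt <- 0.41
  # independent oracle: bisect the force balance directly from the
  # tendon_force / muscle_force primitives (static, v = 0)
  oracle_xi <- function(a) {
    h <- optimal_fascicle_length(a, cst_test) * sin(cst_test$phi0)
    g <- function(l_t) {
      w <- l_mt - l_t
      l_m <- sqrt(w^2 + h^2)
      tendon_force((l_t - ltsk) / ltsk, Fmax) -
        muscle_force(l_m, 0, a, atan2(h, w), cst_test, Fmax)
    }
    lo <- 0.9 * ltsk; hi <- l_mt
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
    }
    ((lo + hi) / 2 - ltsk) / ltsk
  }
  a_grid <- seq(0, 1, by = 0.25)
  xi_pkg <- vapply(a_grid, function(a)
    solve_equilibrium(l_mt, a, NULL, cst_test, ltsk, Fmax)$xi, 1)
  xi_orc <- vapply(a_grid, oracle_xi, 1)
  expect_equal(xi_pkg, xi_orc, tolerance = 1e-6)
  expect_true(all(diff(xi_pkg) >= -1e-12))
})

test_that("compiled trajectory solve matches the per-sample R solver", {
  set.seed(7)
  n <- 40
  q <- pi / 2 + 0.2 * sin(seq(0, 2 * pi, length.out = n))
  lmt <- mtu_length(q, cst_test)
  a <- pmax(0, 0.8 * sin(seq(0, pi, length.out = n)))
  dt <- 0.01
  cpp <- muscle_forward(lmt, a, cst_test, ltsk = 0.35, Fmax = 600, dt = dt)
  prev <- NULL
  for (k in seq_len(n)) {
    s <- solve_equilibrium(lmt[k], a[k], prev, cst_test, 0.35, 600, dt = dt)
    expect_equal(cpp$l_t[k], s$l_t, tolerance = 1e-8)
    expect_equal(cpp$F_mt[k], s$F_mt, tolerance = 1e-5)
    prev <- s
  }
})

test_that("a stiff tendon approaches the rigid-tendon limit", {
  for (cfgi in 1:5) {
    set.seed(cfgi)
    l_mt <- runif(1, 0.40, 0.43)
    a <- runif(1, 0.3, 1)
    s <- solve_equilibrium(l_mt, a, NULL, cst_test, 0.35, 600,
                           tendon_scale = 1e6)
    expect_lt(abs(s$l_t - 0.35), 1e-4)
    expect_lt(abs(s$l_m * cos(s$phi) - (l_mt - 0.35)), 2e-4)
  }
})

test_that("joint moment is the sum of force times moment arm", {
  mk <- function(F) data.frame(F_mt = F)
  expect_equal(joint_moment(list(mk(0), mk(0)), list(0.05, 0.04)), 0)
  expect_equal(joint_moment(list(mk(100)), list(0.05)), 5)
  expect_equal(joint_moment(list(mk(100), mk(75)), list(0.05, 0.04)), 8)
  expect_error(joint_moment(list(mk(c(1, 2)), mk(1)), list(c(0.1, 0.1), 0.1)),
               "alignment")
})
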