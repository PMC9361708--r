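test_that("zero-phase filters have unit DC gain: constant in, same constant out", {
  x <- rep(3.7, 500)
  expect_lt(max(abs(filter_mt(x, fs = 1000) - 3.7)), 1e-9)
  expect_lt(max(abs(filter_mt(x, fs = 100, cutoff = 30) - 3.7)), 1e-9)
})

test_that("envelope of a passband sinusoid approaches the rectified-sine mean", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  x <- sin(2 * pi * 100 * t)
  env <- bandpass_envelope(x, fs = fs)
  interior <- env[round(length(env) * 0.3):round(length(env) * 0.7)]
  expect_lt(max(abs(interior - 2 / pi)) / (2 / pi), 0.05)
})

test_that("envelope pipeline rejects out-of-band and degenerate input", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  # 5 Hz lies below the band: attenuated by >= 20 dB relative to passband
  lo <- bandpass_envelope(sin(2 * pi * 5 * t), fs = fs)
  interior <- function(x) x[round(length(x) * 0.3):round(length(x) * 0.7)]
  expect_lt(max(interior(lo)) / (2 / pi), 0.1)
  # zero in, zero out
  expect_equal(max(abs(bandpass_envelope(rep(0, 1000), fs = fs))), 0)
  # sampling-rate and data errors
  expect_error(bandpass_envelope(rnorm(100), fs = 500), "invalid-rate")
  expect_error(bandpass_envelope(c(1, NA, 2), fs = 1000), "data error")
})

test_that("normalize_envelope scales, clips and validates", {
  expect_equal(normalize_envelope(rep(5, 10), 5), rep(1, 10))
  expect_equal(normalize_envelope(rep(0, 10), 5), rep(0, 10))
  expect_equal(normalize_envelope(6, 5), 1)        # other-trial transient
  expect_error(normalize_envelope(1:5, 0), "config error")
  s <- uniform_series(c(1, 2, 4), fs = 100)
  u <- normalize_envelope(s, 4)
  expect_s3_class(u, "uniform_series")
  expect_equal(u$values, c(0.25, 0.5, 1))
})

test_that("filter_mt smooths jitter and preserves steps", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  mt <- 15 + 0.5 * sin(2 * pi * 1 * t)
  jit <- sin(2 * pi * 200 * t)
  out <- filter_mt(mt + jit, fs = fs)
  interior <- function(x) x[round(length(x) * 0.2):round(length(x) * 0.8)]
  # residual ripple of the 200 Hz component attenuated by >= 20 dB
  expect_lt(max(abs(interior(out - mt))), 0.1)
  # step input settles to the step level (DC gain 1)
  step <- c(rep(10, 1000), rep(12, 1000))
  out2 <- filter_mt(step, fs = fs)
  expect_lt(abs(out2[1500] - 12), 1e-6)
  expect_lt(abs(out2[500] - 10), 1e-6)
})

test_that("segment_stance finds one cycle per load period of a square wave", {
  fs <- 1000
  period <- c(rep(800, 0.6 * fs), rep(0, 0.4 * fs))
  grf <- c(rep(0, 100), rep(period, 4), rep(0, 100))
  st <- segment_stance(grf, fs = fs, threshold = 20)
  expect_equal(nrow(st), 4)
  expect_equal(diff(st$heel_strike_idx), rep(1000, 3))
  expect_equal(st$duration_s, rep(0.6, 4), tolerance = 0.01)
  expect_true(all(st$heel_strike_idx < st$toe_off_idx))
})

test_that("segment_stance edge cases: silence, short blips, truncated contacts", {
  expect_warning(st <- segment_stance(rep(0, 1000), fs = 1000), "no stance")
  expect_equal(nrow(st), 0)
  blip <- c(rep(0, 500), rep(500, 50), rep(0, 500))   # 0.05 s blip
  expect_warning(st2 <- segment_stance(blip, fs = 1000, min_duration = 0.2))
  expect_equal(nrow(st2), 0)
  # contact in progress at either record edge is discarded
  trunc <- c(rep(700, 300), rep(0, 400), rep(700, 300))
  expect_warning(st3 <- segment_stance(trunc, fs = 1000))
  expect_equal(nrow(st3), 0)
})

test_that("cycle counts match a brute-force threshold-crossing oracle", {
  fs <- 200
  set.seed(42)
  for (case in 1:5) {
    on_s <- runif(1, 0.3, 0.8); off_s <- runif(1, 0.2, 0.6)
    k <- sample(2:6, 1)
    grf <- c(rep(0, 50), rep(c(rep(600, round(on_s * fs)),
                               rep(0, round(off_s * fs))), k), rep(0, 50))
    st <- segment_stance(grf, fs = fs)
    # oracle: count maximal runs above threshold not touching the edges
    r <- rle(grf > 20)
    runs <- which(r$values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    full <- runs[starts[runs] > 1 & ends[runs] < length(grf) &
                   r$lengths[runs] / fs >= 0.2]
    expect_equal(nrow(st), length(full))
  }
})

test_that("polyphase resampling preserves a low-frequency tone", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  x <- sin(2 * pi * 3 * t)
  y <- resample_series(x, 100, fs = fs)
  t2 <- seq(0, by = 1 / 100, length.out = length(y))
  interior <- 30:(length(y) - 30)
  expect_lt(max(abs(y[interior] - sin(2 * pi * 3 * t2[interior]))), 0.01)
})
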