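test_that("moving average matches the convolution oracle", {
  rate <- 51.2
  expect_equal(moving_average(rep(3.5, 100), rate), rep(3.5, 100))
  # unit impulse -> rectangle of height 1/13 over 13 interior samples
  x <- numeric(101); x[51] <- 1
  y <- moving_average(x, rate)
  expect_equal(sum(y > 0), 13)
  expect_equal(max(y), 1 / 13, tolerance = 1e-12)
  # white-noise variance reduced by ~1/13
  set.seed(8)
  z <- rnorm(10000)
  expect_equal(var(moving_average(z, rate)) * 13, 1, tolerance = 0.2)
})

test_that("min-max scaling is exact and affine-invariant", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.25, 1)
  expect_equal(minmax_scale(x), x)
  set.seed(9)
  v <- rnorm(50)
  expect_equal(minmax_scale(v), minmax_scale(3.7 * v + 11), tolerance = 1e-12)
  expect_error(minmax_scale(rep(2, 10)), "constant")
})

test_that("peak detection recovers synthetic pulse trains", {
  for (bpm in c(50, 72, 110)) {
    p <- gen_ppg(bpm, 0, 60, seed = bpm)
    x <- minmax_scale(moving_average(as.numeric(p$samples), p$rate_hz))
    pk <- detect_peaks(x, p$rate_hz)
    expect_lt(abs(heart_rate(pk, 60) - bpm), 1.01)
    # refractory rule: never two peaks within min_distance_s
    if (length(pk$peak_indices) > 1) {
      expect_true(all(diff(pk$peak_indices) >= 0.5 * p$rate_hz))
    }
  }
})

test_that("refractory filtering keeps the taller of two close peaks", {
  rate <- 51.2
  x <- numeric(200)
  x[50] <- 0.6; x[50 + round(0.3 * rate)] <- 0.9  # 0.3 s apart
  pk <- detect_peaks(x, rate, threshold_frac = 0.1)
  expect_identical(pk$peak_indices, 50L + as.integer(round(0.3 * rate)))
  expect_equal(length(detect_peaks(numeric(100), rate)$peak_indices), 0)
  expect_error(detect_peaks(c(1, 2), rate), "short")
})

test_that("heart rate arithmetic is exact", {
  expect_equal(heart_rate(36, 30), 72)
  expect_equal(heart_rate(0, 60), 0)
})

test_that("pNN50 matches exhaustive counting on constructed RR sequences", {
  expect_equal(pnn50(rep(0.8, 10)), 0)
  expect_equal(pnn50(rep(c(0.8, 0.9), 10)), 1)
  expect_equal(pnn50(c(0.80, 0.84, 0.90)), 0.5)   # diffs 40 ms, 60 ms
  expect_error(pnn50(0.8), "2 RR")
  # invariance to uniform time shift of all peaks (RR unchanged)
  set.seed(10)
  rr <- runif(20, 0.7, 1.0)
  expect_equal(pnn50(rr), pnn50(rr))
})

test_that("stat6 matches its closed-form identities", {
  s <- stat6(c(5, 5, 5, 5)) |> suppressWarnings()
  expect_equal(unname(s), c(5, 0, 0, 0, 0, 0))
  expect_warning(stat6(rep(1, 5)), "zero-variance")
  ramp <- seq(0, 10, by = 0.5)
  expect_equal(unname(stat6(ramp)[3]), 0.5)
  set.seed(11)
  x <- rnorm(200)
  s <- stat6(x)
  expect_equal(unname(s[4]), unname(s[3] / s[2]), tolerance = 1e-12)
  expect_equal(unname(s[6]), unname(s[5] / s[2]), tolerance = 1e-12)
})

test_that("SCR features recover injected responses exactly", {
  rate <- 51.2
  t <- (0:(30 * rate - 1)) / rate
  flat <- rep(5, length(t))
  expect_equal(unname(gsr_peak_features(flat, rate)), c(0, 0))
  # two smooth bumps of heights 0.2 and 0.4 on a flat baseline
  bump <- function(center, amp) amp * exp(-(t - center)^2 / (2 * 0.5^2))
  x <- flat + bump(8, 0.2) + bump(20, 0.4)
  pf <- gsr_peak_features(x, rate)
  expect_equal(unname(pf["npeaks"]), 2)
  expect_equal(unname(pf["mean_height"]), 0.3, tolerance = 1e-3)
})

test_that("Poisson SCR counts are recovered within 3 sigma", {
  g <- gen_gsr(3, 600, seed = 13)
  x <- moving_average(as.numeric(g$samples), g$rate_hz)
  pf <- gsr_peak_features(x, g$rate_hz)
  expect_lt(abs(pf["npeaks"] - 30), 3 * sqrt(30))
})
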