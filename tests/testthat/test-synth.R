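test_that("generation is reproducible and schema-stable across seeds", {
  a <- gen_eeg("high", NULL, 3, seed = 40)
  b <- gen_eeg("high", NULL, 3, seed = 40)
  expect_identical(a$samples, b$samples)
  c <- gen_eeg("high", NULL, 3, seed = 41)
  expect_false(identical(a$samples, c$samples))
  expect_equal(ncol(a$samples), 14)
  expect_equal(a$rate_hz, 128)

  d1 <- gen_dataset(generator_config(seed = 1, n_subjects = 3, trials_per_subject = 4,
                                     incidents_per_subject = 2))
  d2 <- gen_dataset(generator_config(seed = 2, n_subjects = 3, trials_per_subject = 4,
                                     incidents_per_subject = 2))
  expect_identical(names(d1$trials), names(d2$trials))
  expect_false(identical(d1$subjects$hr_bpm, d2$subjects$hr_bpm))
  expect_equal(sum(d1$trials$task == "attention"), 12)
  expect_equal(sum(d1$trials$task == "incident"), 6)
})

test_that("zero effect leaves band power label-independent; strong effect separates", {
  ratio <- function(lbl, seed, effect) {
    e <- gen_eeg(lbl, NULL, 6, seed = seed, effect = effect)
    f <- bandpass_eeg(e$samples, rate_hz = 128)
    sum(band_psd(f, "beta", rate_hz = 128)) / sum(band_psd(f, "alpha", rate_hz = 128))
  }
  hi0 <- vapply(1:60, function(i) ratio("high", i, 0), numeric(1))
  lo0 <- vapply(1:60, function(i) ratio("low", 1000 + i, 0), numeric(1))
  # effect 0: class means equal within 3 sigma of the difference
  se <- sqrt(var(hi0) / 60 + var(lo0) / 60)
  expect_lt(abs(mean(hi0) - mean(lo0)), 3 * se)
  # effect 1: beta/alpha ratio alone separates with AUC > 0.9
  hi1 <- vapply(1:60, function(i) ratio("high", 2000 + i, 1), numeric(1))
  lo1 <- vapply(1:60, function(i) ratio("low", 3000 + i, 1), numeric(1))
  expect_gt(auc(c(hi1, lo1), rep(c(1, -1), each = 60)), 0.9)
})

test_that("PPG generator round-trips through the cardio pipeline", {
  p <- gen_ppg(72, 0, 60, seed = 42)
  x <- minmax_scale(moving_average(as.numeric(p$samples), p$rate_hz))
  pk <- detect_peaks(x, p$rate_hz)
  expect_lt(abs(heart_rate(pk, 60) - 72), 1.01)
  expect_equal(pnn50(pk$rr_intervals_s), 0)
  # alternating jitter: every successive RR difference exceeds 50 ms
  p2 <- gen_ppg(72, 0.06, 60, seed = 43, jitter_mode = "alternating")
  x2 <- minmax_scale(moving_average(as.numeric(p2$samples), p2$rate_hz))
  pk2 <- detect_peaks(x2, p2$rate_hz)
  expect_equal(pnn50(pk2$rr_intervals_s), 1)
  expect_error(gen_ppg(30, 0, 10), "40")
})

test_that("GSR generator honors the SCR rate", {
  g0 <- gen_gsr(0, 60, seed = 44)
  x0 <- moving_average(as.numeric(g0$samples), g0$rate_hz)
  expect_equal(unname(gsr_peak_features(x0, g0$rate_hz)), c(0, 0))
  expect_equal(nrow(g0$samples), round(60 * 51.2))
})

test_that("landmark generator produces label-dependent expression magnitude", {
  still <- gen_landmarks("low", 30, seed = 45, jitter_px = 0, amplitude_px = 0)
  agg <- aggregate_trial(geometric_features(still))
  expect_true(all(abs(agg$std_vec) < 1e-12))
  expect_equal(dim(gen_landmarks("high", 60, seed = 46)$points)[1], 60)
  # hazard frames at 30 fps for 2 s
  ds <- gen_dataset(generator_config(seed = 3, n_subjects = 1, trials_per_subject = 1,
                                     incidents_per_subject = 1))
  inc <- materialize_trial(ds, which(ds$trials$task == "incident")[1], "face")
  expect_equal(dim(inc$face$points)[1], 60)
})

test_that("sidecar ground truth matches measured observables", {
  ds <- gen_dataset(generator_config(seed = 4, n_subjects = 2, trials_per_subject = 2,
                                     incidents_per_subject = 0,
                                     attention_duration_range = c(30, 30)))
  for (r in 1:2) {
    tr <- materialize_trial(ds, r, "ppg")
    x <- minmax_scale(moving_average(as.numeric(tr$ppg$samples), tr$ppg$rate_hz))
    hr <- heart_rate(detect_peaks(x, tr$ppg$rate_hz), 30)
    expect_lt(abs(hr - ds$trials$truth_hr_bpm[r]), 2)
  }
  # alpha multiplier ordering is reflected in measured alpha power
  ds2 <- gen_dataset(generator_config(seed = 5, n_subjects = 1, trials_per_subject = 6,
                                      incidents_per_subject = 0,
                                      attention_duration_range = c(8, 8)))
  alpha <- vapply(1:6, function(r) {
    tr <- materialize_trial(ds2, r, "eeg")
    mean(band_psd(bandpass_eeg(tr$eeg$samples, rate_hz = 128), "alpha", rate_hz = 128))
  }, numeric(1))
  truth <- ds2$trials$truth_alpha_mult[1:6]
  hi <- truth > median(truth)
  # larger alpha multiplier (low-attention trials) means more alpha power
  expect_gt(mean(alpha[hi]), mean(alpha[!hi]))
})
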