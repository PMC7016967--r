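test_that("write/read round trip preserves samples to full precision", {
  ds <- gen_dataset(generator_config(seed = 5, n_subjects = 1, trials_per_subject = 2,
                                     incidents_per_subject = 0,
                                     attention_duration_range = c(3, 4)))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir, task = "attention")
  rec <- read_recording(manifest_path = file.path(dir, "S01", "manifest.json"))
  expect_identical(sort(names(rec$streams)), c("eeg", "gsr", "ppg"))
  expect_identical(rec$streams$eeg$channel_names, eeg_channel_names())
  t1 <- materialize_trial(ds, 1)
  n1 <- nrow(t1$eeg$samples)
  expect_identical(rec$streams$eeg$samples[seq_len(n1), ], t1$eeg$samples)
  expect_identical(as.numeric(rec$streams$ppg$samples)[seq_len(nrow(t1$ppg$samples))],
                   as.numeric(t1$ppg$samples))
  # second write/read cycle is idempotent
  write_recording(rec, file.path(dir, "again"))
  rec2 <- read_recording(manifest_path = file.path(dir, "again", "manifest.json"))
  expect_identical(rec2$streams$eeg$samples, rec$streams$eeg$samples)
  expect_identical(rec2$landmarks$points, rec$landmarks$points)
})

test_that("reading an EEG table with a missing electrode names it", {
  ds <- gen_dataset(generator_config(seed = 6, n_subjects = 1, trials_per_subject = 1,
                                     incidents_per_subject = 0,
                                     attention_duration_range = c(3, 3)))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir, task = "attention", modalities = "eeg")
  tab <- read.csv(file.path(dir, "S01", "eeg.csv"), check.names = FALSE)
  tab$F7 <- NULL
  write.csv(tab, file.path(dir, "S01", "eeg.csv"), row.names = FALSE)
  expect_error(read_recording(manifest_path = file.path(dir, "S01", "manifest.json")),
               "F7")
})

test_that("a non-monotone time column is rejected", {
  ds <- gen_dataset(generator_config(seed = 7, n_subjects = 1, trials_per_subject = 1,
                                     incidents_per_subject = 0,
                                     attention_duration_range = c(3, 3)))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir, task = "attention", modalities = "eeg")
  tab <- read.csv(file.path(dir, "S01", "eeg.csv"), check.names = FALSE)
  tab$time_s[5] <- tab$time_s[3]
  write.csv(tab, file.path(dir, "S01", "eeg.csv"), row.names = FALSE)
  expect_error(read_recording(manifest_path = file.path(dir, "S01", "manifest.json")),
               "increasing")
})

test_that("trial slices have round(duration x rate) samples per modality", {
  streams <- list(
    eeg = signal_stream(matrix(rnorm(128 * 10 * 14), ncol = 14), 128,
                        eeg_channel_names(), "eeg"),
    ppg = signal_stream(rnorm(512), 51.2, "ppg", "ppg"))
  rec <- recording("SX", streams)
  sl <- segment_trials(rec, data.frame(t_start_s = 1, t_end_s = 3,
                                       hazard_label = "hazardous"))
  expect_equal(nrow(sl[[1]]$streams$eeg), 256)   # 2 s x 128 Hz
  expect_equal(nrow(sl[[1]]$streams$ppg), 102)   # round-half-away(102.4)
})

test_that("segmentation is content-independent: covering slices concatenate back", {
  m <- matrix(rnorm(128 * 9 * 2), ncol = 2)
  rec <- recording("SX", list(eeg = signal_stream(m, 128, c("AF3", "AF4"), "eeg")))
  specs <- data.frame(t_start_s = c(0, 2, 5), t_end_s = c(2, 5, 9))
  sl <- segment_trials(rec, specs)
  rebuilt <- do.call(rbind, lapply(sl, function(t) t$streams$eeg))
  expect_identical(unname(rebuilt), unname(m))
})

test_that("invalid trial specs fail loudly", {
  rec <- recording("SX", list(ppg = signal_stream(rnorm(512), 51.2, "ppg", "ppg")))
  expect_error(segment_trials(rec, data.frame(t_start_s = 2, t_end_s = 2)), "exceed")
  expect_error(segment_trials(rec, data.frame(t_start_s = 5, t_end_s = 60)), "outside")
  expect_error(segment_trials(rec, data.frame(t_start_s = 0, t_end_s = 3,
                                              hazard_label = "hazardous")),
               "2 s")
})

test_that("the study-scale manifest has 12 subjects x 35 = 420 attention trials", {
  ds <- gen_dataset(generator_config(seed = 1))
  att <- ds$trials[ds$trials$task == "attention", ]
  expect_equal(nrow(att), 420)
  expect_equal(length(unique(att$subject)), 12)
  expect_true(all(table(att$subject) == 35))
  # 20 low / 15 high per subject, per the stimulus annotation ratios
  tab <- table(att$subject, att$attention_label)
  expect_true(all(tab[, "low"] == 20) && all(tab[, "high"] == 15))
})

test_that("sample-count rounding is half away from zero", {
  expect_identical(round_half_away(c(102.4, 102.5, 0.5, -0.5, -2.5)),
                   c(102L, 103L, 1L, -1L, -3L))
})
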