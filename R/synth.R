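#' Synthetic dataset generator configuration
#'
#' Study-scale defaults emulate the cohort design: 12 subjects, 35
#' attention-labelled trials each (20 requiring low and 15 high attention;
#' durations drawn from 14-50 s, spanning the two stimulus sets) and 70
#' two-second incident trials each (30 hazardous, 40 non-hazardous). Class
#' effects are injected into physiologically meaningful observables -- EEG
#' band power (alpha down, beta up for high attention / hazardous), facial
#' expression excursion magnitude -- so feature extraction is genuinely
#' exercised; `*_effect = 0` makes the label-conditional distributions
#' identical. One global seed fans out deterministically to per-subject,
#' per-trial, per-modality sub-seeds.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_subject attention trials per subject.
#' @param incidents_per_subject 2-s incident trials per subject.
#' @param attention_effect,hazard_effect non-negative effect sizes (0 = no
#'   class difference; 1 = the default strong effect, roughly halving alpha
#'   and doubling beta power and 2.5x-ing expression excursions).
#' @param subject_variability lognormal sd of subject-specific gains.
#' @param base_hr_bpm resting heart rate.
#' @param hrv_level fractional RR jitter.
#' @param scr_rate_per_min skin-conductance response rate.
#' @param attention_duration_range attention-trial duration range, seconds.
#' @param incident_duration_s incident-trial duration (2 s by design).
#' @param eeg_rate_hz,ppg_rate_hz,gsr_rate_hz sampling rates.
#' @param fps landmark frame rate.
#' @param landmark_jitter_px per-frame landmark jitter sd, pixels.
#' @param expression_amplitude_px baseline expression excursion, pixels.
#' @param seed global seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 12, trials_per_subject = 35,
                             incidents_per_subject = 70,
                             attention_effect = 1, hazard_effect = 1,
                             subject_variability = 0.2,
                             base_hr_bpm = 72, hrv_level = 0.04,
                             scr_rate_per_min = 3,
                             attention_duration_range = c(14, 50),
                             incident_duration_s = 2,
                             eeg_rate_hz = 128, ppg_rate_hz = 51.2,
                             gsr_rate_hz = 51.2, fps = 30,
                             landmark_jitter_px = 0.5,
                             expression_amplitude_px = 3,
                             seed = 1) {
  stopifnot(attention_effect >= 0, hazard_effect >= 0, n_subjects >= 1)
  structure(as.list(environment()), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d subjects x (%d attention + %d incident) trials, effects a=%g h=%g, seed %d\n",
              x$n_subjects, x$trials_per_subject, x$incidents_per_subject,
              x$attention_effect, x$hazard_effect, x$seed))
  invisible(x)
}

# class multiplier on band amplitudes: high/hazardous shifts alpha down,
# beta up, symmetric on the log scale
band_multipliers <- function(active, effect) {
  z <- as.numeric(active)
  c(theta = 1, alpha = exp(-0.35 * effect * z), beta = exp(0.35 * effect * z))
}

#' Generate a synthetic 14-channel EEG trial
#'
#' Pink (1/f-like) background noise per channel plus three band-limited
#' oscillatory components (theta 6 Hz, alpha 10 Hz, beta 20 Hz bands) with
#' realistic topographies (alpha posterior-dominant, beta fronto-central,
#' theta frontal), each a mixture of a spatially shared source and an
#' independent per-channel component. "High attention" / "hazardous" trials
#' scale alpha amplitude down and beta up by `exp(+-0.35 * effect)`;
#' subject-specific per-band gains multiply on top.
#'
#' @param trial_label `"low"`/`"high"` (attention) or
#'   `"non_hazardous"`/`"hazardous"`.
#' @param subject_params list with `band_gain` (length-3 multiplier) as
#'   drawn by [gen_dataset()]; `NULL` for unit gains.
#' @param duration_s trial length in seconds (at least 2).
#' @param seed integer seed.
#' @param effect class effect size.
#' @param rate_hz sampling rate.
#' @return a [signal_stream()] with the canonical 14-channel montage.
#' @export
gen_eeg <- function(trial_label, subject_params = NULL, duration_s = 10,
                    seed = 1, effect = 1, rate_hz = 128) {
  if (duration_s < 2) stopf("duration_s must be at least 2 s")
  n <- round_half_away(duration_s * rate_hz)
  active <- trial_label %in% c("high", "hazardous")
  mult <- band_multipliers(active, effect)
  gain <- if (is.null(subject_params)) c(1, 1, 1) else subject_params$band_gain
  mont <- eeg_montage()
  # band topographies over the 14 electrodes (row order = canonical montage)
  topo <- rbind(theta = 0.4 + 0.6 * pmax(mont$y, 0),
                alpha = 0.3 + 0.7 * pmax(-mont$y, 0),
                beta = 0.5 + 0.5 * (1 - abs(mont$y)))
  bands <- list(theta = c(4, 7), alpha = c(8, 12), beta = c(16, 24))
  amp <- c(theta = 4, alpha = 8, beta = 3)
  with_seed(seed, {
    eeg <- matrix(0, n, 14)
    for (ch in 1:14) {
      # leaky-integrated white noise gives a 1/f-like background
      eeg[, ch] <- as.numeric(stats::filter(rnorm(n, sd = 2), 0.95,
                                            method = "recursive"))
    }
    for (b in 1:3) {
      shared <- bandpass_eeg(rnorm(n), bands[[b]][1], bands[[b]][2],
                             rate_hz = rate_hz, order = 2)
      scale_b <- amp[b] * mult[b] * gain[b]
      for (ch in 1:14) {
        own <- bandpass_eeg(rnorm(n), bands[[b]][1], bands[[b]][2],
                            rate_hz = rate_hz, order = 2)
        eeg[, ch] <- eeg[, ch] + scale_b * topo[b, ch] * (0.8 * shared + 0.6 * own)
      }
    }
    signal_stream(eeg, rate_hz, eeg_channel_names(), "eeg")
  })
}

#' Generate a synthetic PPG pulse train
#'
#' Periodic pulse waveform (gamma-shaped systolic peak per beat) with RR
#' jitter scaled by `hrv_level`, plus slow baseline wander and sensor noise.
#' `jitter_mode = "gaussian"` draws independent fractional RR perturbations;
#' `"alternating"` lengthens and shortens alternate beats by exactly
#' `hrv_level * RR`, so every successive RR difference is
#' `2 * hrv_level * 60 / hr_bpm` seconds (the construction used to pin
#' pNN50 at 1).
#'
#' @param hr_bpm mean heart rate (40-180).
#' @param hrv_level fractional RR variability (0 = metronomic).
#' @param duration_s signal length, seconds.
#' @param seed integer seed.
#' @param rate_hz sampling rate.
#' @param jitter_mode `"gaussian"` or `"alternating"`.
#' @return a [signal_stream()] (modality `"ppg"`).
#' @export
gen_ppg <- function(hr_bpm = 72, hrv_level = 0.04, duration_s = 60, seed = 1,
                    rate_hz = 51.2, jitter_mode = c("gaussian", "alternating")) {
  if (hr_bpm < 40 || hr_bpm > 180) stopf("hr_bpm must lie in [40, 180]")
  jitter_mode <- match.arg(jitter_mode)
  base_rr <- 60 / hr_bpm
  n <- round_half_away(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  with_seed(seed, {
    n_beats <- ceiling(duration_s / base_rr) + 3
    jit <- switch(jitter_mode,
                  gaussian = pmax(pmin(rnorm(n_beats), 3), -3) * hrv_level,
                  alternating = hrv_level * (-1)^(seq_len(n_beats)))
    rr <- base_rr * (1 + jit)
    beats <- cumsum(c(0.2, rr))
    beats <- beats[beats < duration_s + base_rr]
    x <- numeric(n)
    tau <- 0.12
    for (bt in beats) {
      rel <- t - bt
      in_pulse <- rel >= 0 & rel < 0.6
      r <- rel[in_pulse] / tau
      x[in_pulse] <- x[in_pulse] + r * exp(1 - r)
    }
    x <- x + 0.15 * sin(2 * pi * 0.08 * t + runif(1, 0, 2 * pi)) + rnorm(n, sd = 0.02)
    signal_stream(x, rate_hz, "ppg", "ppg")
  })
}

#' Generate a synthetic skin-conductance trace
#'
#' Slow tonic drift (a smooth sigmoidal level change) plus Poisson-timed
#' phasic skin-conductance responses with a fast half-cosine rise and
#' exponential decay, plus small sensor noise.
#'
#' @param scr_rate_per_min mean SCR event rate (0 = tonic only).
#' @param duration_s signal length, seconds.
#' @param seed integer seed.
#' @param rate_hz sampling rate.
#' @param tonic_level baseline conductance level (arbitrary microsiemens).
#' @param drift total tonic drift over the trace.
#' @param amp_range SCR amplitude range (uniform).
#' @return a [signal_stream()] (modality `"gsr"`).
#' @export
gen_gsr <- function(scr_rate_per_min = 3, duration_s = 60, seed = 1,
                    rate_hz = 51.2, tonic_level = 5, drift = 0.3,
                    amp_range = c(0.1, 0.5)) {
  if (scr_rate_per_min < 0) stopf("scr_rate_per_min must be non-negative")
  n <- round_half_away(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  with_seed(seed, {
    x <- tonic_level + drift * plogis((t - duration_s / 2) / (duration_s / 8))
    n_ev <- rpois(1, scr_rate_per_min * duration_s / 60)
    if (n_ev > 0) {
      times <- sort(runif(n_ev, 1, max(1.5, duration_s - 5)))
      amps <- runif(n_ev, amp_range[1], amp_range[2])
      for (k in seq_len(n_ev)) {
        rel <- t - times[k]
        rise <- rel >= 0 & rel < 0.7
        x[rise] <- x[rise] + amps[k] * 0.5 * (1 - cos(pi * rel[rise] / 0.7))
        dec <- rel >= 0.7
        x[dec] <- x[dec] + amps[k] * exp(-(rel[dec] - 0.7) / 2.5)
      }
    }
    x <- x + rnorm(n, sd = 0.002)
    signal_stream(x, rate_hz, "gsr", "gsr")
  })
}

#' Generate a synthetic landmark sequence
#'
#' Canonical symmetric face plus a smooth expression displacement (brow
#' raise and mouth opening driven by a slow random sinusoid) whose magnitude
#' grows with the class effect on hazardous / high-attention trials, plus
#' per-frame isotropic landmark jitter. The face box is fixed at 200 x 200.
#'
#' @param trial_label `"low"`/`"high"` or `"non_hazardous"`/`"hazardous"`.
#' @param n_frames number of frames (at least 2).
#' @param seed integer seed.
#' @param effect class effect size.
#' @param fps frame rate.
#' @param jitter_px per-frame jitter sd in pixels.
#' @param amplitude_px baseline expression excursion in pixels.
#' @param subject_gain subject-specific expression gain.
#' @return a [landmark_sequence()].
#' @export
gen_landmarks <- function(trial_label, n_frames, seed = 1, effect = 1,
                          fps = 30, jitter_px = 0.5, amplitude_px = 3,
                          subject_gain = 1) {
  if (n_frames < 2) stopf("n_frames must be at least 2")
  active <- trial_label %in% c("high", "hazardous")
  amp <- amplitude_px * (1 + 1.5 * effect * as.numeric(active)) * subject_gain
  tmpl <- face_landmark_template()
  g <- face_landmark_groups()
  with_seed(seed, {
    tt <- (seq_len(n_frames) - 1) / fps
    f1 <- runif(1, 0.2, 0.5)
    course <- sin(2 * pi * f1 * tt + runif(1, 0, 2 * pi)) +
      0.4 * sin(2 * pi * 2 * f1 * tt + runif(1, 0, 2 * pi))
    pts <- array(rep(tmpl, each = n_frames), c(n_frames, 49, 2))
    brow <- c(g$left_brow, g$right_brow)
    mouth_low <- c(g$lower_lip, g$inner_bottom, 40L, 42L)
    pts[, brow, 2] <- pts[, brow, 2] - amp * course            # brow raise
    pts[, mouth_low, 2] <- pts[, mouth_low, 2] + amp * abs(course)  # mouth open
    if (jitter_px > 0) {
      pts <- pts + array(rnorm(length(pts), sd = jitter_px), dim(pts))
    }
    landmark_sequence(pts, face_w = 200, face_h = 200, fps = fps)
  })
}

#' Generate a full synthetic multimodal dataset
#'
#' Builds the trial manifest (attention and incident tasks, labels, tags,
#' durations), draws per-subject gain parameters, and records a ground-truth
#' sidecar (per-trial heart rate, band multipliers, SCR rate, expression
#' amplitude) for oracle tests. Signals are materialized lazily per trial
#' with [materialize_trial()] so study-scale datasets need not be held in
#' memory; [write_dataset()] renders subjects to disk in the plain-text
#' layout [read_recording()] reads.
#'
#' @param config a [generator_config()].
#' @return object of class `aware_dataset`: `config`, `subjects`
#'   (data.frame of per-subject parameters), `trials` (manifest with labels
#'   and sidecar truth columns).
#' @export
gen_dataset <- function(config = generator_config()) {
  cfg <- config
  subj_ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
  subjects <- data.frame(subject = subj_ids, stringsAsFactors = FALSE)
  sv <- cfg$subject_variability
  gains <- t(vapply(seq_len(cfg$n_subjects), function(s) {
    with_seed(sub_seed(cfg$seed, s, 0, 0),
              c(exp(rnorm(3, 0, sv)), exp(rnorm(1, 0, sv)),
                cfg$base_hr_bpm * exp(rnorm(1, 0, sv / 2))))
  }, numeric(5)))
  subjects$gain_theta <- gains[, 1]
  subjects$gain_alpha <- gains[, 2]
  subjects$gain_beta <- gains[, 3]
  subjects$gain_expr <- gains[, 4]
  subjects$hr_bpm <- pmin(pmax(gains[, 5], 50), 110)

  trials <- list()
  for (s in seq_len(cfg$n_subjects)) {
    # attention task: 20 low / 15 high over 35 videos, 15 kitti / 20 lisa
    natt <- cfg$trials_per_subject
    n_high <- round(natt * 15 / 35)
    att_labels <- with_seed(sub_seed(cfg$seed, s, 0, 1),
                            sample(c(rep("high", n_high), rep("low", natt - n_high))))
    durs <- with_seed(sub_seed(cfg$seed, s, 0, 2),
                      round(runif(natt, cfg$attention_duration_range[1],
                                  cfg$attention_duration_range[2])))
    tags <- rep(c("kitti", "lisa"), length.out = natt)
    trials[[length(trials) + 1]] <- data.frame(
      subject = subj_ids[s], task = "attention",
      trial = seq_len(natt), dataset_tag = tags,
      duration_s = durs, attention_label = att_labels,
      hazard_label = NA_character_, stringsAsFactors = FALSE)
    # incident task: 2-s instances, ~30/70 hazardous
    ninc <- cfg$incidents_per_subject
    if (ninc > 0) {
      n_haz <- round(ninc * 30 / 70)
      inc_labels <- with_seed(sub_seed(cfg$seed, s, 0, 3),
                              sample(c(rep("hazardous", n_haz),
                                       rep("non_hazardous", ninc - n_haz))))
      trials[[length(trials) + 1]] <- data.frame(
        subject = subj_ids[s], task = "incident",
        trial = seq_len(ninc), dataset_tag = rep(c("kitti", "lisa"), length.out = ninc),
        duration_s = cfg$incident_duration_s, attention_label = NA_character_,
        hazard_label = inc_labels, stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL
  # sidecar ground truth
  sidx <- match(trials$subject, subjects$subject)
  label <- ifelse(trials$task == "attention", trials$attention_label, trials$hazard_label)
  eff <- ifelse(trials$task == "attention", cfg$attention_effect, cfg$hazard_effect)
  active <- label %in% c("high", "hazardous")
  trials$truth_hr_bpm <- subjects$hr_bpm[sidx]
  trials$truth_alpha_mult <- exp(-0.35 * eff * active) * subjects$gain_alpha[sidx]
  trials$truth_beta_mult <- exp(0.35 * eff * active) * subjects$gain_beta[sidx]
  trials$truth_scr_rate <- cfg$scr_rate_per_min
  trials$truth_expr_amp <- cfg$expression_amplitude_px *
    (1 + 1.5 * eff * active) * subjects$gain_expr[sidx]

  structure(list(config = cfg, subjects = subjects, trials = trials),
            class = "aware_dataset")
}

#' @export
print.aware_dataset <- function(x, ...) {
  cat(sprintf("<aware_dataset> %d subjects, %d attention + %d incident trials (seed %d)\n",
              nrow(x$subjects), sum(x$trials$task == "attention"),
              sum(x$trials$task == "incident"), x$config$seed))
  invisible(x)
}

#' Materialize one trial's signals
#'
#' Generates the requested modalities for a single manifest row using the
#' dataset's deterministic per-trial sub-seeds.
#'
#' @param dataset an `aware_dataset`.
#' @param row row index into `dataset$trials`.
#' @param modalities subset of `c("eeg", "ppg", "gsr", "face")`.
#' @return named list of [signal_stream()]s / a [landmark_sequence()]
#'   (under `face`), plus `label` and the manifest row under `meta`.
#' @export
materialize_trial <- function(dataset, row,
                              modalities = c("eeg", "ppg", "gsr", "face")) {
  cfg <- dataset$config
  tr <- dataset$trials[row, ]
  s <- match(tr$subject, dataset$subjects$subject)
  sp <- dataset$subjects[s, ]
  task_code <- if (tr$task == "attention") 1L else 2L
  label <- if (tr$task == "attention") tr$attention_label else tr$hazard_label
  eff <- if (tr$task == "attention") cfg$attention_effect else cfg$hazard_effect
  out <- list()
  if ("eeg" %in% modalities) {
    out$eeg <- gen_eeg(label,
                       subject_params = list(band_gain = c(sp$gain_theta, sp$gain_alpha, sp$gain_beta)),
                       duration_s = tr$duration_s,
                       seed = sub_seed(cfg$seed, s, tr$trial, task_code * 10 + 1),
                       effect = eff, rate_hz = cfg$eeg_rate_hz)
  }
  if ("ppg" %in% modalities) {
    out$ppg <- gen_ppg(sp$hr_bpm, cfg$hrv_level, tr$duration_s,
                       seed = sub_seed(cfg$seed, s, tr$trial, task_code * 10 + 2),
                       rate_hz = cfg$ppg_rate_hz)
  }
  if ("gsr" %in% modalities) {
    out$gsr <- gen_gsr(cfg$scr_rate_per_min, tr$duration_s,
                       seed = sub_seed(cfg$seed, s, tr$trial, task_code * 10 + 3),
                       rate_hz = cfg$gsr_rate_hz)
  }
  if ("face" %in% modalities) {
    out$face <- gen_landmarks(label, n_frames = max(2, round_half_away(tr$duration_s * cfg$fps)),
                              seed = sub_seed(cfg$seed, s, tr$trial, task_code * 10 + 4),
                              effect = eff, fps = cfg$fps,
                              jitter_px = cfg$landmark_jitter_px,
                              amplitude_px = cfg$expression_amplitude_px,
                              subject_gain = sp$gain_expr)
  }
  out$label <- label
  out$meta <- tr
  out
}

#' Write a synthetic dataset to disk
#'
#' Renders each subject's trials as one continuous recording (trials
#' concatenated back-to-back) in the plain-text CSV/JSON layout of
#' [write_recording()], plus `trials.csv` (the manifest with per-recording
#' start/end times) and `config.json`.
#'
#' @param dataset an `aware_dataset`.
#' @param dir output directory.
#' @param task which task's trials to render.
#' @param modalities modalities to render.
#' @param subjects subset of subject ids (default all).
#' @return invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir, task = "attention",
                          modalities = c("eeg", "ppg", "gsr", "face"),
                          subjects = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- dataset$config
  if (is.null(subjects)) subjects <- dataset$subjects$subject
  man_rows <- list()
  for (sid in subjects) {
    rows <- which(dataset$trials$subject == sid & dataset$trials$task == task)
    parts <- lapply(rows, materialize_trial, dataset = dataset, modalities = modalities)
    streams <- list()
    for (mod in intersect(modalities, c("eeg", "ppg", "gsr"))) {
      samp <- do.call(rbind, lapply(parts, function(p) p[[mod]]$samples))
      streams[[mod]] <- signal_stream(samp, parts[[1]][[mod]]$rate_hz,
                                      parts[[1]][[mod]]$channel_names, mod)
    }
    landmarks <- NULL
    if ("face" %in% modalities) {
      pts <- do.call(abind_frames, lapply(parts, function(p) p$face$points))
      landmarks <- landmark_sequence(pts, 200, 200, fps = cfg$fps)
    }
    rec <- recording(sid, streams, landmarks)
    write_recording(rec, file.path(dir, sid))
    t0 <- cumsum(c(0, head(dataset$trials$duration_s[rows], -1)))
    man_rows[[sid]] <- cbind(dataset$trials[rows, ],
                             t_start_s = t0,
                             t_end_s = t0 + dataset$trials$duration_s[rows])
  }
  man <- do.call(rbind, man_rows)
  rownames(man) <- NULL
  utils::write.csv(man, file.path(dir, "trials.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

abind_frames <- function(...) {
  mats <- list(...)
  n <- sum(vapply(mats, function(m) dim(m)[1], numeric(1)))
  out <- array(0, c(n, 49, 2))
  at <- 0
  for (m in mats) {
    k <- dim(m)[1]
    out[(at + 1):(at + k), , ] <- m
    at <- at + k
  }
  out
}
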