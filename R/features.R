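# Normalize trial containers: materialize_trial() lists and segment_trials()
# "trial" objects both yield list(samples, rate_hz) per signal modality and a
# landmark_sequence under "face".
trial_stream <- function(trial, mod) {
  if (mod == "face") {
    lm <- if (!is.null(trial$face)) trial$face else trial$landmarks
    if (is.null(lm)) stopf("trial has no landmark data")
    return(lm)
  }
  st <- if (!is.null(trial$streams)) trial$streams[[mod]] else trial[[mod]]
  if (is.null(st)) stopf("trial has no %s stream", mod)
  if (inherits(st, "signal_stream")) {
    list(samples = st$samples, rate_hz = st$rate_hz)
  } else {
    list(samples = as.matrix(st), rate_hz = attr(st, "rate_hz"))
  }
}

default_method <- function(modality) {
  switch(modality, eeg = "entropy", ppg = "hrv_stat", gsr = "hrv_stat",
         face = "geometric", stopf("unknown modality '%s'", modality))
}

#' Extract one feature block from a trial
#'
#' Dispatches to the per-modality extractors: EEG `"entropy"`
#' (band-pass 4-45 Hz then the 91 conditional-entropy pair features) or
#' `"deep_psd"` (band-power topomap image through the embedder); PPG
#' `"hrv_stat"` (heart rate, pNN50 and the six statistical descriptors after
#' 0.25-s moving-average filtering and min-max scaling) or `"spectro_deep"`
#' (0-5 Hz spectrogram image through the embedder); GSR `"hrv_stat"`
#' (SCR peak count/mean height plus the six descriptors) or `"spectro_deep"`
#' (0-2 Hz); face `"geometric"` (30 landmark features aggregated to 90) or
#' `"deep_face"` (framewise embeddings of rendered landmark images
#' aggregated to 12288).
#'
#' @param trial a trial from [materialize_trial()] or [segment_trials()].
#' @param modality `"eeg"`, `"ppg"`, `"gsr"` or `"face"`.
#' @param method extraction method (defaults per modality).
#' @param embedder an [image_embedder()] for the deep methods.
#' @param bin_count histogram bins for the entropy method.
#' @param frame_stride take every k-th frame for `"deep_face"`.
#' @return a [feature_block()].
#' @export
extract_trial_features <- function(trial, modality, method = NULL,
                                   embedder = NULL, bin_count = 16,
                                   frame_stride = 1) {
  if (is.null(method)) method <- default_method(modality)
  if (modality == "eeg") {
    st <- trial_stream(trial, "eeg")
    filt <- bandpass_eeg(st$samples, 4, 45, rate_hz = st$rate_hz)
    if (method == "entropy") {
      return(conditional_entropy_vector(filt, bin_count))
    } else if (method == "deep_psd") {
      win <- if (nrow(filt) >= st$rate_hz) 1 else NULL
      th <- band_psd(filt, "theta", rate_hz = st$rate_hz, window_s = win)
      al <- band_psd(filt, "alpha", rate_hz = st$rate_hz, window_s = win)
      be <- band_psd(filt, "beta", rate_hz = st$rate_hz, window_s = win)
      v <- embed(topomap_rgb(th, al, be)$pixels, embedder)
      return(feature_block("eeg", "deep_psd", v, sprintf("psd_img_%04d", seq_along(v))))
    }
  } else if (modality %in% c("ppg", "gsr")) {
    st <- trial_stream(trial, modality)
    x <- moving_average(as.numeric(st$samples), st$rate_hz, 0.25)
    if (method == "hrv_stat") {
      if (modality == "ppg") {
        xs <- minmax_scale(x)
        pk <- detect_peaks(xs, st$rate_hz)
        hr <- heart_rate(pk, length(xs) / st$rate_hz)
        pn <- if (length(pk$rr_intervals_s) >= 2) pnn50(pk$rr_intervals_s) else 0
        s6 <- stat6(xs)
        return(feature_block("ppg", "hrv_stat", c(hr, pn, s6),
                             c("ppg_hr", "ppg_pnn50", paste0("ppg_stat", 1:6))))
      } else {
        pk <- gsr_peak_features(x, st$rate_hz)
        s6 <- stat6(x)
        return(feature_block("gsr", "hrv_stat", c(pk, s6),
                             c("gsr_npeaks", "gsr_meanpeak", paste0("gsr_stat", 1:6))))
      }
    } else if (method == "spectro_deep") {
      fmax <- if (modality == "ppg") 5 else 2
      img <- spectrogram_image(x, st$rate_hz, fmax)
      v <- embed(img$pixels, embedder)
      return(feature_block(modality, "spectro_deep", v,
                           sprintf("%s_img_%04d", modality, seq_along(v))))
    }
  } else if (modality == "face") {
    lm <- trial_stream(trial, "face")
    if (method == "geometric") {
      agg <- aggregate_trial(geometric_features(lm))
      return(feature_block("face", "geometric", agg$block, names(agg$block)))
    } else if (method == "deep_face") {
      idx <- seq(1, dim(lm$points)[1], by = frame_stride)
      imgs <- lapply(idx, function(i) {
        render_face_image(lm$points[i, , ], lm$face_w[i], lm$face_h[i])
      })
      M <- face_embedding_sequence(imgs, embedder)
      colnames(M) <- sprintf("vggf_%04d", seq_len(ncol(M)))
      agg <- aggregate_trial(M)
      return(feature_block("face", "deep_face", agg$block, names(agg$block)))
    }
  }
  stopf("unknown modality/method combination: %s/%s", modality, method)
}

#' Extract a per-trial feature table from a dataset
#'
#' Materializes each trial of the requested task, extracts the requested
#' feature blocks and fuses them by concatenation into one row per trial.
#'
#' @param dataset an `aware_dataset` from [gen_dataset()].
#' @param task `"attention"` or `"incident"`.
#' @param modalities modalities to extract.
#' @param methods named list of methods per modality (defaults per
#'   modality).
#' @param embedder an [image_embedder()] (needed for deep methods).
#' @param bin_count histogram bins for entropy features.
#' @return data.frame: `subject`, `trial`, `label` (+1 = high attention /
#'   hazardous) and one column per feature.
#' @export
extract_features <- function(dataset, task = "attention",
                             modalities = "eeg", methods = list(),
                             embedder = NULL, bin_count = 16) {
  check_task_modalities(task, modalities)
  rows <- which(dataset$trials$task == task)
  if (length(rows) == 0) stopf("dataset has no '%s' trials", task)
  feats <- vector("list", length(rows))
  labels <- numeric(length(rows))
  for (k in seq_along(rows)) {
    tr <- materialize_trial(dataset, rows[k], modalities = modalities)
    blocks <- lapply(modalities, function(mod) {
      method <- if (!is.null(methods[[mod]])) methods[[mod]] else default_method(mod)
      extract_trial_features(tr, mod, method, embedder = embedder,
                             bin_count = bin_count)
    })
    feats[[k]] <- do.call(c, lapply(blocks, function(b) b$values))
    labels[k] <- if (tr$label %in% c("high", "hazardous")) 1 else -1
  }
  X <- do.call(rbind, feats)
  out <- data.frame(subject = dataset$trials$subject[rows],
                    trial = dataset$trials$trial[rows],
                    label = labels, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(X))
}

check_task_modalities <- function(task, modalities) {
  if (task == "incident" && any(modalities %in% c("ppg", "gsr"))) {
    stopf(paste0("PPG and GSR do not provide the fine temporal resolution ",
                 "needed for 2-s incident trials (2 s spans only 2-4 ",
                 "heartbeats and GSR changes over several seconds); use eeg ",
                 "and/or face for the incident task"))
  }
  invisible(TRUE)
}

#' Extract windowed EEG topomap-embedding sequences
#'
#' The trend-based temporal representation: each trial is split into
#' contiguous windows ([topomap_sequence()]), each window's topomap is
#' embedded, and the per-trial result is a `windows x 4096` matrix ready for
#' PCA reduction to 60 per-step features and LSTM classification.
#'
#' @param dataset an `aware_dataset`.
#' @param task `"attention"` or `"incident"`.
#' @param windows_per_second windows per second (1 for attention-length
#'   trials, 30 for 2-s incidents).
#' @param embedder an [image_embedder()].
#' @return list with `sequences` (list of matrices), `labels` (+1/-1),
#'   `subjects`.
#' @export
extract_sequences <- function(dataset, task = "incident",
                              windows_per_second = 30, embedder = NULL) {
  rows <- which(dataset$trials$task == task)
  if (length(rows) == 0) stopf("dataset has no '%s' trials", task)
  seqs <- vector("list", length(rows))
  labels <- numeric(length(rows))
  for (k in seq_along(rows)) {
    tr <- materialize_trial(dataset, rows[k], modalities = "eeg")
    filt <- bandpass_eeg(tr$eeg$samples, 4, 45, rate_hz = tr$eeg$rate_hz)
    maps <- topomap_sequence(filt, windows_per_second, rate_hz = tr$eeg$rate_hz)
    seqs[[k]] <- do.call(rbind, lapply(maps, function(m) embed(m$pixels, embedder)))
    labels[k] <- if (tr$label %in% c("high", "hazardous")) 1 else -1
  }
  list(sequences = seqs, labels = labels, subjects = dataset$trials$subject[rows])
}

#' Leave-one-subject-out CV for sequence features
#'
#' Per fold: the scaler and the PCA-to-`n_components` basis are fitted on
#' the training subjects' stacked window features, every sequence is
#' transformed, an LSTM is trained on the training sequences and evaluated
#' on the held-out subject.
#'
#' @param sequences list of `windows x p` matrices.
#' @param y labels +1/-1.
#' @param subjects subject id per sequence.
#' @param n_components per-step PCA dimensionality (default 60).
#' @param spec an [lstm_spec()] (its `input_dim` must equal
#'   `n_components`).
#' @param fit_scope `"train_only"` or `"global"`.
#' @return a `cv_result` as from [loso_cv()].
#' @export
loso_cv_sequences <- function(sequences, y, subjects, n_components = 60,
                              spec = lstm_spec(input_dim = n_components),
                              fit_scope = c("train_only", "global")) {
  fit_scope <- match.arg(fit_scope)
  folds <- loso_folds(subjects)
  acc <- numeric(length(folds)); aucs <- rep(NA_real_, length(folds))
  ntest <- integer(length(folds))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    fit_idx <- if (fit_scope == "global") seq_along(sequences) else tr
    stacked <- do.call(rbind, sequences[fit_idx])
    nf <- normalize_fit(stacked)
    k <- min(n_components, nrow(stacked) - 1L, ncol(stacked))
    pf <- pca_fit(normalize_apply(stacked, nf), k)
    reduce <- function(s) pca_apply(normalize_apply(s, nf), pf)
    sp <- spec; sp$input_dim <- as.integer(k)
    model <- lstm_train(lapply(sequences[tr], reduce), y[tr], sp)
    pred <- lstm_predict(model, lapply(sequences[te], reduce))
    acc[f] <- 100 * mean(pred$label == y[te])
    if (length(unique(y[te])) == 2) aucs[f] <- auc(pred$score, y[te])
    ntest[f] <- length(te)
  }
  per <- data.frame(subject = names(folds), n_test = ntest,
                    accuracy = acc, auc = aucs, stringsAsFactors = FALSE)
  structure(list(per_subject = per,
                 mean_accuracy = mean(acc), sd_accuracy = sd(acc),
                 mean_auc = mean(aucs, na.rm = TRUE),
                 sd_auc = sd(aucs[!is.na(aucs)]),
                 fold_sizes = data.frame(subject = names(folds),
                                         n_train = lengths(lapply(folds, `[[`, "train")),
                                         n_test = ntest)),
            class = "cv_result")
}
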