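#' Signal stream container
#'
#' A single-modality multichannel signal: a numeric sample matrix (rows =
#' samples, columns = channels), a sampling rate and channel names. EEG streams
#' carry 14 channels at 128 Hz in this study design; PPG and GSR are
#' single-channel at 51.2 Hz.
#'
#' @param samples numeric vector (single channel) or matrix, rows = samples.
#' @param rate_hz positive sampling rate in Hz.
#' @param channel_names character labels, one per column.
#' @param modality one of `"eeg"`, `"ppg"`, `"gsr"`.
#' @return an object of class `signal_stream` with elements `samples`
#'   (matrix), `rate_hz`, `channel_names`, `modality`.
#' @examples
#' s <- signal_stream(matrix(rnorm(256 * 2), ncol = 2), 128,
#'                    c("AF3", "AF4"), "eeg")
#' s
#' @export
signal_stream <- function(samples, rate_hz, channel_names = NULL,
                          modality = c("eeg", "ppg", "gsr")) {
  modality <- match.arg(modality)
  if (is.null(dim(samples))) samples <- matrix(as.numeric(samples), ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is_scalar_number(rate_hz) || rate_hz <= 0) {
    stopf("rate_hz must be a single positive number, got %s", format(rate_hz))
  }
  if (is.null(channel_names)) {
    channel_names <- if (ncol(samples) == 1) modality else
      paste0(modality, seq_len(ncol(samples)))
  }
  if (length(channel_names) != ncol(samples)) {
    stopf("%d channel names for %d channels", length(channel_names), ncol(samples))
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stopf("signal samples must be finite")
  }
  colnames(samples) <- channel_names
  structure(list(samples = samples, rate_hz = rate_hz,
                 channel_names = channel_names, modality = modality),
            class = "signal_stream")
}

#' @export
print.signal_stream <- function(x, ...) {
  cat(sprintf("<signal_stream> %s: %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              x$modality, ncol(x$samples), nrow(x$samples), x$rate_hz,
              nrow(x$samples) / x$rate_hz))
  invisible(x)
}

stream_duration <- function(stream) nrow(stream$samples) / stream$rate_hz

# Require the canonical 14-channel montage, reordering columns into canonical
# order if needed. Errors name any missing electrode.
check_eeg_montage <- function(stream) {
  canon <- eeg_channel_names()
  missing <- setdiff(canon, stream$channel_names)
  if (length(missing) > 0) {
    stopf("EEG stream is missing electrode(s): %s", paste(missing, collapse = ", "))
  }
  if (!identical(stream$channel_names, canon)) {
    stream$samples <- stream$samples[, canon, drop = FALSE]
    stream$channel_names <- canon
  }
  stream
}

#' Landmark sequence container
#'
#' Per-frame facial landmarks: 49 (x, y) pixel coordinates per frame plus the
#' detected face-box width and height (minimum face size 50 x 50 pixels).
#'
#' @param points numeric array `n_frames x 49 x 2` (last dim = x, y).
#' @param face_w,face_h face-box dimensions in pixels, length 1 or `n_frames`.
#' @param fps frame rate (frames per second).
#' @param t0_s timestamp of the first frame, seconds from recording start.
#' @return object of class `landmark_sequence`.
#' @export
landmark_sequence <- function(points, face_w, face_h, fps = 30, t0_s = 0) {
  if (length(dim(points)) != 3 || dim(points)[2] != 49 || dim(points)[3] != 2) {
    stopf("points must be an n_frames x 49 x 2 array, got dims [%s]",
          paste(dim(points), collapse = ", "))
  }
  n <- dim(points)[1]
  face_w <- rep_len(as.numeric(face_w), n)
  face_h <- rep_len(as.numeric(face_h), n)
  if (any(face_w < 50) || any(face_h < 50)) {
    stopf("face box below the 50 x 50 pixel minimum face size")
  }
  structure(list(points = points, face_w = face_w, face_h = face_h,
                 fps = fps, t0_s = t0_s,
                 timestamp_s = t0_s + (seq_len(n) - 1) / fps),
            class = "landmark_sequence")
}

#' @export
print.landmark_sequence <- function(x, ...) {
  cat(sprintf("<landmark_sequence> %d frames x 49 points @ %g fps\n",
              dim(x$points)[1], x$fps))
  invisible(x)
}

#' Multimodal recording container
#'
#' One subject's synchronized streams (any of eeg/ppg/gsr) plus an optional
#' landmark sequence. Time is seconds from recording start for all modalities.
#'
#' @param subject_id subject identifier.
#' @param streams named list of [signal_stream()] objects keyed by modality.
#' @param landmarks optional [landmark_sequence()].
#' @return object of class `recording`.
#' @export
recording <- function(subject_id, streams, landmarks = NULL) {
  if (!is.list(streams) || length(streams) == 0) stopf("streams must be a non-empty list")
  for (nm in names(streams)) {
    st <- streams[[nm]]
    if (!inherits(st, "signal_stream")) stopf("stream '%s' is not a signal_stream", nm)
    if (!identical(st$modality, nm)) stopf("stream '%s' has modality '%s'", nm, st$modality)
  }
  if (!is.null(landmarks) && !inherits(landmarks, "landmark_sequence")) {
    stopf("landmarks must be a landmark_sequence")
  }
  structure(list(subject_id = subject_id, streams = streams,
                 landmarks = landmarks),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s\n", x$subject_id))
  for (st in x$streams) print(st)
  if (!is.null(x$landmarks)) print(x$landmarks)
  invisible(x)
}

recording_duration <- function(rec) {
  min(vapply(rec$streams, stream_duration, numeric(1)))
}

#' Named per-trial feature vector
#'
#' Carries a block of extracted features together with its modality and
#' extraction-method provenance. All values must be finite.
#'
#' @param modality one of eeg/ppg/gsr/face.
#' @param method extraction method tag (e.g. `"entropy"`, `"hrv_stat"`,
#'   `"geometric"`, `"deep_psd"`, `"spectro_deep"`, `"deep_face"`).
#' @param values numeric vector.
#' @param names labels, same length as `values`.
#' @param trial_ref optional trial identifier.
#' @return object of class `feature_block`.
#' @export
feature_block <- function(modality, method, values, names, trial_ref = NULL) {
  values <- as.numeric(values)
  if (length(values) != length(names)) {
    stopf("feature_block: %d values but %d names", length(values), length(names))
  }
  if (any(!is.finite(values))) stopf("feature_block contains non-finite values")
  names(values) <- names
  structure(list(trial_ref = trial_ref, modality = modality, method = method,
                 values = values),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block> %s/%s: %d features\n",
              x$modality, x$method, length(x$values)))
  invisible(x)
}
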