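#' Write a recording to plain-text tables
#'
#' Writes one delimited CSV per signal stream (time column plus one column per
#' channel, '.' decimal, header row), a long-format landmark table
#' (`frame, point, x, y, face_w, face_h`) and a JSON manifest declaring
#' modalities and sampling rates. Values are written with 17 significant
#' digits so a read/write round trip reproduces doubles exactly.
#'
#' @param rec a [recording()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(subject_id = rec$subject_id, streams = list())
  for (mod in names(rec$streams)) {
    st <- rec$streams[[mod]]
    file <- paste0(mod, ".csv")
    n <- nrow(st$samples)
    tab <- cbind(time_s = (seq_len(n) - 1) / st$rate_hz, st$samples)
    write_full_precision(tab, file.path(dir, file))
    manifest$streams[[mod]] <- list(modality = mod, file = file,
                                    rate_hz = st$rate_hz,
                                    channels = st$channel_names)
  }
  if (!is.null(rec$landmarks)) {
    lm <- rec$landmarks
    n <- dim(lm$points)[1]
    tab <- cbind(frame = rep(seq_len(n) - 1L, each = 49),
                 point = rep(0:48, times = n),
                 x = as.vector(t(lm$points[, , 1])),
                 y = as.vector(t(lm$points[, , 2])),
                 face_w = rep(lm$face_w, each = 49),
                 face_h = rep(lm$face_h, each = 49))
    write_full_precision(tab, file.path(dir, "landmarks.csv"))
    manifest$landmarks <- list(file = "landmarks.csv", fps = lm$fps, t0_s = lm$t0_s)
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_full_precision <- function(tab, path) {
  tab <- as.matrix(tab)
  txt <- apply(tab, 2, function(col) formatC(col, digits = 17, format = "g"))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = 1)
  lines <- c(paste(colnames(tab), collapse = ","),
             apply(txt, 1, paste, collapse = ","))
  writeLines(lines, path)
}

#' Read a recording from plain-text tables
#'
#' Inverse of [write_recording()]. Signal tables must have a header row and a
#' monotone `time_s` column consistent with the manifest's declared sampling
#' rate; EEG tables must contain all 14 canonical electrodes (a missing
#' electrode is reported by name).
#'
#' @param signal_table_paths named character vector of CSV paths keyed by
#'   modality, or `NULL` to resolve files from the manifest's directory.
#' @param landmark_table_path path to the landmark table, or `NULL`.
#' @param manifest_path path to the JSON manifest.
#' @return a [recording()].
#' @export
read_recording <- function(signal_table_paths = NULL, landmark_table_path = NULL,
                           manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  base <- dirname(manifest_path)
  streams <- list()
  for (mod in names(man$streams)) {
    decl <- man$streams[[mod]]
    path <- if (!is.null(signal_table_paths) && mod %in% names(signal_table_paths)) {
      signal_table_paths[[mod]]
    } else file.path(base, decl$file)
    tab <- read.csv(path, check.names = FALSE)
    if (!"time_s" %in% names(tab)) stopf("%s: no 'time_s' column", path)
    t <- tab$time_s
    if (length(t) > 1 && any(diff(t) <= 0)) {
      stopf("%s: time column is not strictly increasing", path)
    }
    rate <- as.numeric(decl$rate_hz)
    if (length(t) > 1) {
      implied <- 1 / median(diff(t))
      if (abs(implied - rate) / rate > 1e-3) {
        stopf("%s: time column implies %.4f Hz but manifest declares %g Hz",
              path, implied, rate)
      }
    }
    chans <- unlist(decl$channels)
    missing <- setdiff(chans, names(tab))
    if (length(missing) > 0) {
      stopf("%s: missing channel column(s): %s", path, paste(missing, collapse = ", "))
    }
    st <- signal_stream(as.matrix(tab[, chans, drop = FALSE]), rate, chans, mod)
    if (mod == "eeg") st <- check_eeg_montage(st)
    streams[[mod]] <- st
  }
  landmarks <- NULL
  if (!is.null(man$landmarks)) {
    path <- if (!is.null(landmark_table_path)) landmark_table_path else
      file.path(base, man$landmarks$file)
    tab <- read.csv(path)
    frames <- sort(unique(tab$frame))
    n <- length(frames)
    if (nrow(tab) != n * 49) stopf("%s: expected 49 points per frame", path)
    ord <- order(tab$frame, tab$point)
    tab <- tab[ord, ]
    pts <- array(0, c(n, 49, 2))
    pts[, , 1] <- matrix(tab$x, nrow = n, byrow = TRUE)
    pts[, , 2] <- matrix(tab$y, nrow = n, byrow = TRUE)
    landmarks <- landmark_sequence(pts,
                                   face_w = tab$face_w[seq(1, nrow(tab), by = 49)],
                                   face_h = tab$face_h[seq(1, nrow(tab), by = 49)],
                                   fps = man$landmarks$fps,
                                   t0_s = if (is.null(man$landmarks$t0_s)) 0 else man$landmarks$t0_s)
  }
  recording(man$subject_id, streams, landmarks)
}

#' Segment a recording into labelled trials
#'
#' Slices every stream (and the landmark sequence, if present) of a recording
#' at the trial boundaries given in `trial_specs`. The number of samples in a
#' slice is `round_half_away(duration * rate)` per modality (so a 2-s slice of
#' a 51.2 Hz stream has 102 samples); start offsets are rounded the same way,
#' making disjoint covering trials concatenate back to the original stream
#' whenever boundaries fall on integer sample counts.
#'
#' @param rec a [recording()].
#' @param trial_specs data.frame with columns `t_start_s`, `t_end_s` and
#'   optionally `trial_id`, `dataset_tag`, `attention_label`, `hazard_label`.
#' @return list of `trial` objects: each holds `subject_id`, labels, times and
#'   a `streams` list of sample matrices (with `rate_hz` attributes) plus
#'   `landmarks`.
#' @export
segment_trials <- function(rec, trial_specs) {
  trial_specs <- as.data.frame(trial_specs)
  dur <- recording_duration(rec)
  # rounding each modality's sample count can leave the recording a fraction
  # of a sample short of the nominal duration; allow one sample of slack at
  # the slowest rate
  tol <- max(1 / vapply(rec$streams, function(s) s$rate_hz, numeric(1)))
  out <- vector("list", nrow(trial_specs))
  for (i in seq_len(nrow(trial_specs))) {
    sp <- trial_specs[i, ]
    t0 <- sp$t_start_s; t1 <- sp$t_end_s
    if (!is.finite(t0) || !is.finite(t1) || t1 <= t0) {
      stopf("trial %d: t_end_s (%g) must exceed t_start_s (%g)", i, t1, t0)
    }
    if (t0 < 0 || t1 > dur + tol) {
      stopf("trial %d: [%g, %g] s lies outside the %.3f s recording", i, t0, t1, dur)
    }
    hazard <- if ("hazard_label" %in% names(sp)) sp$hazard_label else NA
    if (!is.na(hazard) && abs((t1 - t0) - 2) > 1e-9) {
      stopf("trial %d: incident trials must be exactly 2 s long, got %g s", i, t1 - t0)
    }
    slices <- list()
    for (mod in names(rec$streams)) {
      st <- rec$streams[[mod]]
      i0 <- round_half_away(t0 * st$rate_hz)
      ns <- round_half_away((t1 - t0) * st$rate_hz)
      if (ns < 1) stopf("trial %d: zero-length slice for %s", i, mod)
      if (i0 + ns > nrow(st$samples)) ns <- nrow(st$samples) - i0
      sl <- st$samples[(i0 + 1):(i0 + ns), , drop = FALSE]
      attr(sl, "rate_hz") <- st$rate_hz
      slices[[mod]] <- sl
    }
    lms <- NULL
    if (!is.null(rec$landmarks)) {
      lm <- rec$landmarks
      f0 <- round_half_away((t0 - lm$t0_s) * lm$fps)
      nf <- round_half_away((t1 - t0) * lm$fps)
      f0 <- max(f0, 0)
      nf <- min(nf, dim(lm$points)[1] - f0)
      idx <- (f0 + 1):(f0 + nf)
      lms <- landmark_sequence(lm$points[idx, , , drop = FALSE],
                               lm$face_w[idx], lm$face_h[idx],
                               fps = lm$fps, t0_s = t0)
    }
    out[[i]] <- structure(list(
      subject_id = rec$subject_id,
      trial_id = if ("trial_id" %in% names(sp)) sp$trial_id else i,
      dataset_tag = if ("dataset_tag" %in% names(sp)) sp$dataset_tag else "synthetic",
      t_start_s = t0, t_end_s = t1,
      attention_label = if ("attention_label" %in% names(sp)) sp$attention_label else NA,
      hazard_label = hazard,
      streams = slices, landmarks = lms), class = "trial")
  }
  out
}

#' @export
print.trial <- function(x, ...) {
  cat(sprintf("<trial> %s #%s [%g, %g] s attention=%s hazard=%s (%s)\n",
              x$subject_id, x$trial_id, x$t_start_s, x$t_end_s,
              x$attention_label, x$hazard_label,
              paste(names(x$streams), collapse = "+")))
  invisible(x)
}
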