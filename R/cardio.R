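#' Centered moving-average filter
#'
#' Moving mean with a window of `round_half_away(window_s * rate_hz)` samples
#' (13 samples for the default 0.25 s at 51.2 Hz), centered, with edges
#' handled by shrinking the window. Output has the input's length.
#'
#' @param x numeric vector.
#' @param rate_hz sampling rate in Hz.
#' @param window_s window length in seconds; `window_s * rate_hz` must be at
#'   least 1.
#' @return filtered numeric vector.
#' @export
moving_average <- function(x, rate_hz, window_s = 0.25) {
  w <- round_half_away(window_s * rate_hz)
  if (w < 1) stopf("window of %g s at %g Hz is shorter than one sample", window_s, rate_hz)
  n <- length(x)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Min-max scaling to [0, 1]
#'
#' Affine map sending the observed minimum to 0 and maximum to 1; invariant
#' to any positive affine transformation of the input.
#'
#' @param x non-constant numeric vector.
#' @return numeric vector in [0, 1].
#' @export
minmax_scale <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) stopf("constant signal: min-max scaling has zero range")
  (x - r[1]) / (r[2] - r[1])
}

#' Peak detection with a refractory constraint
#'
#' Local maxima above an adaptive threshold (a configurable fraction of the
#' rolling 90th percentile of the signal), thinned so that no two detected
#' peaks are closer than `min_distance_s` -- where two candidates conflict,
#' the taller one is kept. Intended for min-max-scaled pulse signals; the
#' 0.5 s default refractory distance suppresses false positives between
#' heartbeats.
#'
#' @param x numeric signal (scaled to [0, 1] for the default threshold to be
#'   meaningful).
#' @param rate_hz sampling rate in Hz.
#' @param min_distance_s minimum spacing between detected peaks, seconds.
#' @param threshold_frac threshold as a fraction of the rolling 90th
#'   percentile.
#' @param baseline_window_s window for the rolling percentile, seconds.
#' @return object of class `peak_set`: `peak_indices` (strictly increasing),
#'   `peak_heights`, `rr_intervals_s`, `min_distance_s`, `rate_hz`.
#' @export
detect_peaks <- function(x, rate_hz, min_distance_s = 0.5,
                         threshold_frac = 0.5, baseline_window_s = 10) {
  n <- length(x)
  if (n < 3) stopf("signal too short for peak detection (%d samples)", n)
  thr <- threshold_frac * rolling_quantile(x, rate_hz, baseline_window_s, 0.9)
  dx <- diff(x)
  cand <- which(dx[-length(dx)] > 0 & dx[-1] <= 0) + 1L
  cand <- cand[x[cand] > thr[cand]]
  min_gap <- min_distance_s * rate_hz
  keep <- integer(0)
  if (length(cand) > 0) {
    for (i in cand[order(x[cand], decreasing = TRUE)]) {
      if (all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
    }
    keep <- sort(keep)
  }
  structure(list(peak_indices = keep, peak_heights = x[keep],
                 rr_intervals_s = if (length(keep) > 1) diff(keep) / rate_hz else numeric(0),
                 min_distance_s = min_distance_s, rate_hz = rate_hz),
            class = "peak_set")
}

# chunked rolling quantile: exact quantile per window-sized chunk, linearly
# interpolated between chunk centers
rolling_quantile <- function(x, rate_hz, window_s, prob) {
  n <- length(x)
  w <- max(2L, min(n, round_half_away(window_s * rate_hz)))
  starts <- seq(1L, n, by = w)
  centers <- pmin(starts + (w - 1L) / 2, n)
  q <- vapply(starts, function(s) quantile(x[s:min(s + w - 1L, n)], prob, names = FALSE),
              numeric(1))
  if (length(q) == 1) return(rep(q, n))
  approx(centers, q, xout = seq_len(n), rule = 2)$y
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks, min spacing %g s\n",
              length(x$peak_indices), x$min_distance_s))
  invisible(x)
}

#' Heart rate from a peak set
#'
#' Peaks per minute: `count * 60 / duration_s`.
#'
#' @param peaks a `peak_set` (or a bare count).
#' @param duration_s signal duration in seconds.
#' @return heart rate in beats per minute.
#' @export
heart_rate <- function(peaks, duration_s) {
  if (duration_s <= 0) stopf("duration_s must be positive")
  count <- if (inherits(peaks, "peak_set")) length(peaks$peak_indices) else peaks
  count * 60 / duration_s
}

#' pNN50 heart-rate variability
#'
#' Fraction of successive RR-interval differences exceeding 50 ms:
#' `(# |diff(RR)| > 0.05 s) / (length(RR) - 1)`. Reported as a fraction in
#' [0, 1].
#'
#' @param rr_intervals_s RR intervals in seconds (at least 2).
#' @return fraction in [0, 1].
#' @export
pnn50 <- function(rr_intervals_s) {
  if (inherits(rr_intervals_s, "peak_set")) rr_intervals_s <- rr_intervals_s$rr_intervals_s
  if (length(rr_intervals_s) < 2) {
    stopf("need at least 2 RR intervals, got %d", length(rr_intervals_s))
  }
  mean(abs(diff(rr_intervals_s)) > 0.05)
}

#' Six time-domain statistical descriptors
#'
#' The classic six-statistic set over a signal and its difference series:
#' (1) mean, (2) standard deviation, (3) mean absolute first difference,
#' (4) mean absolute first difference of the standardized signal,
#' (5) mean absolute second difference, (6) mean absolute second difference
#' of the standardized signal. Features 4 and 6 equal features 3 and 5
#' divided by the standard deviation; for a zero-variance signal they are set
#' to 0 with a warning.
#'
#' @param x numeric vector of length at least 3.
#' @return named numeric vector of length 6 (`mean`, `sd`, `mad1`,
#'   `mad1_std`, `mad2`, `mad2_std`).
#' @export
stat6 <- function(x) {
  if (length(x) < 3) stopf("need at least 3 samples, got %d", length(x))
  mu <- mean(x)
  s <- sd(x)
  d1 <- mean(abs(diff(x)))
  d2 <- mean(abs(diff(x, differences = 2)))
  if (s == 0) {
    warnf("zero-variance signal: standardized difference features set to 0")
    d1s <- 0; d2s <- 0
  } else {
    d1s <- d1 / s; d2s <- d2 / s
  }
  c(mean = mu, sd = s, mad1 = d1, mad1_std = d1s, mad2 = d2, mad2_std = d2s)
}
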