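#' Zero-phase Butterworth band-pass for EEG
#'
#' 4th-order Butterworth applied forward-backward (zero phase, so the
#' effective magnitude response is squared), with odd-reflection padding at
#' the edges. The default 4-45 Hz band keeps theta through low gamma.
#'
#' @param x a [signal_stream()], or a numeric matrix/vector with `rate_hz`.
#' @param lo_hz,hi_hz band edges in Hz; `hi_hz` must be below Nyquist.
#' @param rate_hz sampling rate, required when `x` is not a signal_stream.
#' @param order filter order (per pass).
#' @return same container type as `x`, filtered, same length.
#' @export
bandpass_eeg <- function(x, lo_hz = 4, hi_hz = 45, rate_hz = NULL, order = 4) {
  if (inherits(x, "signal_stream")) {
    rate_hz <- x$rate_hz
    x$samples <- bandpass_eeg(x$samples, lo_hz, hi_hz, rate_hz = rate_hz, order = order)
    return(x)
  }
  if (is.null(rate_hz)) stopf("rate_hz required for matrix input")
  if (hi_hz >= rate_hz / 2) {
    stopf("hi_hz (%g) must be below the Nyquist frequency (%g)", hi_hz, rate_hz / 2)
  }
  if (lo_hz <= 0 || lo_hz >= hi_hz) stopf("need 0 < lo_hz < hi_hz")
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else x
  bf <- signal::butter(order, c(lo_hz, hi_hz) / (rate_hz / 2), type = "pass")
  n <- nrow(m)
  pad <- min(n - 1, max(1L, round_half_away(3 * rate_hz / lo_hz)))
  out <- apply(m, 2, function(col) {
    # odd reflection padding keeps edges free of filter start-up transients
    pre <- 2 * col[1] - col[(pad + 1):2]
    post <- 2 * col[n] - col[(n - 1):(n - pad)]
    y <- signal::filtfilt(bf, c(pre, col, post))
    y[(pad + 1):(pad + n)]
  })
  if (vec) as.numeric(out) else out
}

#' Amplitude-threshold artifact rejection
#'
#' Lightweight artifact handling: samples whose per-channel z-score exceeds
#' `z_thresh` in magnitude are flagged and replaced by linear interpolation
#' over the surrounding clean samples.
#'
#' @param x [signal_stream()] or numeric matrix/vector.
#' @param z_thresh positive z-score threshold.
#' @return list with `stream` (cleaned, same container type) and `mask`
#'   (logical, TRUE where samples were replaced).
#' @export
amplitude_reject <- function(x, z_thresh = 5) {
  if (z_thresh <= 0) stopf("z_thresh must be positive")
  if (inherits(x, "signal_stream")) {
    res <- amplitude_reject(x$samples, z_thresh)
    x$samples <- res$stream
    return(list(stream = x, mask = res$mask))
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else x
  mask <- matrix(FALSE, nrow(m), ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    s <- sd(col)
    if (s == 0) next
    z <- (col - mean(col)) / s
    bad <- abs(z) > z_thresh
    if (!any(bad)) next
    if (all(bad)) stopf("channel %d: every sample exceeds the threshold; cannot interpolate", j)
    idx <- seq_along(col)
    m[bad, j] <- approx(idx[!bad], col[!bad], xout = idx[bad], rule = 2)$y
    mask[, j] <- bad
  }
  if (vec) list(stream = as.numeric(m), mask = as.logical(mask))
  else list(stream = m, mask = mask)
}
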