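#' EEG frequency bands and their display colors
#'
#' The three bands encoded in the topographic RGB image: theta (4-7 Hz, red),
#' alpha (7-13 Hz, green) and beta (13-30 Hz, blue).
#'
#' @return data.frame with columns `name`, `lo_hz`, `hi_hz`, `color_channel`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("theta", "alpha", "beta"),
             lo_hz = c(4, 7, 13), hi_hz = c(7, 13, 30),
             color_channel = c("R", "G", "B"),
             stringsAsFactors = FALSE)
}

# Welch PSD with Hann windows (one-sided density). window_s = NULL gives a
# plain periodogram over the whole signal. Short windows are zero-padded to
# nfft_min points so narrow bands always contain frequency bins.
welch_psd <- function(x, rate, window_s = 1, overlap = 0.5, nfft_min = 256) {
  n <- length(x)
  L <- if (is.null(window_s)) n else min(n, max(2L, round_half_away(window_s * rate)))
  hop <- max(1L, round_half_away(L * (1 - overlap)))
  starts <- seq(0L, n - L, by = hop)
  if (is.null(window_s)) starts <- 0L
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  if (L == 2) w <- c(1, 1)  # degenerate Hann would be all-zero
  nfft <- max(L, nfft_min)
  nf <- nfft %/% 2 + 1
  acc <- numeric(nf)
  scale <- rate * sum(w^2)
  for (s0 in starts) {
    seg <- x[(s0 + 1):(s0 + L)] * w
    X <- fft(c(seg, numeric(nfft - L)))
    P <- Mod(X[1:nf])^2 / scale
    if (nf > 2) P[2:(nf - 1)] <- 2 * P[2:(nf - 1)]  # one-sided
    acc <- acc + P
  }
  list(freq = (0:(nf - 1)) * rate / nfft, psd = acc / length(starts))
}

#' Mean in-band power spectral density per channel
#'
#' Welch PSD (1-s Hann windows, 50% overlap by default) averaged over the
#' frequency bins falling inside the band, one value per channel. With
#' `window_s = NULL` a single zero-padded periodogram over the whole segment
#' is used instead (the sub-second-window regime of [topomap_sequence()]).
#'
#' @param x [signal_stream()] or samples-by-channels matrix.
#' @param band numeric `c(lo_hz, hi_hz)`, or a band name from [eeg_bands()].
#' @param rate_hz sampling rate (taken from the stream when given one).
#' @param window_s Welch window length in seconds, or `NULL` for a plain
#'   periodogram.
#' @param overlap fractional window overlap.
#' @return numeric vector of non-negative mean in-band PSD values, one per
#'   channel.
#' @export
band_psd <- function(x, band, rate_hz = NULL, window_s = 1, overlap = 0.5) {
  if (inherits(x, "signal_stream")) {
    rate_hz <- x$rate_hz
    x <- x$samples
  }
  if (is.null(rate_hz)) stopf("rate_hz required for matrix input")
  if (is.character(band)) {
    bands <- eeg_bands()
    if (!band %in% bands$name) stopf("unknown band '%s'", band)
    band <- unlist(bands[bands$name == band, c("lo_hz", "hi_hz")])
  }
  if (band[2] > rate_hz / 2 + 1e-9) {
    stopf("band [%g, %g] Hz exceeds the Nyquist frequency (%g Hz)",
          band[1], band[2], rate_hz / 2)
  }
  m <- if (is.null(dim(x))) matrix(x, ncol = 1) else x
  if (!is.null(window_s) && nrow(m) < rate_hz) {
    stopf("trial shorter than 1 s; use window_s = NULL for sub-second segments")
  }
  vapply(seq_len(ncol(m)), function(j) {
    sp <- welch_psd(m[, j], rate_hz, window_s = window_s, overlap = overlap)
    sel <- sp$freq >= band[1] & sp$freq < band[2]
    if (!any(sel)) return(0)
    mean(sp$psd[sel])
  }, numeric(1))
}
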