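#' Short-time Fourier magnitude over a capped frequency range
#'
#' Hann-windowed STFT magnitudes, cropped to frequencies at or below
#' `f_max_hz`. This is the numeric layer underneath [spectrogram_image()];
#' it is exposed so the spectral content can be checked without the colormap
#' and resampling steps.
#'
#' @param x numeric signal.
#' @param rate_hz sampling rate in Hz.
#' @param f_max_hz highest rendered frequency (must not exceed Nyquist).
#' @param window_s STFT window length, seconds.
#' @param overlap fractional window overlap.
#' @return list `mag` (freq x frames matrix), `freq`, `times` (window
#'   centers, seconds).
#' @export
spectrogram_matrix <- function(x, rate_hz, f_max_hz, window_s = 4, overlap = 0.75) {
  if (f_max_hz > rate_hz / 2) {
    stopf("f_max_hz (%g) exceeds the Nyquist frequency (%g)", f_max_hz, rate_hz / 2)
  }
  n <- length(x)
  L <- round_half_away(window_s * rate_hz)
  if (L < 4) stopf("window of %g s at %g Hz is too short", window_s, rate_hz)
  hop <- max(1L, round_half_away(L * (1 - overlap)))
  if (n < L + hop) {
    stopf("signal (%d samples) shorter than two STFT windows (window %d, hop %d)",
          n, L, hop)
  }
  starts <- seq(0L, n - L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  nf <- L %/% 2 + 1
  freq <- (0:(nf - 1)) * rate_hz / L
  sel <- freq <= f_max_hz
  mag <- matrix(0, sum(sel), length(starts))
  for (k in seq_along(starts)) {
    seg <- x[(starts[k] + 1):(starts[k] + L)] * w
    X <- fft(seg)
    mag[, k] <- Mod(X[1:nf])[sel]
  }
  list(mag = mag, freq = freq[sel], times = (starts + L / 2) / rate_hz)
}

#' Spectrogram RGB image
#'
#' STFT magnitude cropped to `[0, f_max_hz]` (5 Hz for PPG, 2 Hz for GSR),
#' log-scaled (`log10(mag + 1e-8)`), min-max normalized, mapped through a
#' perceptually-uniform colormap and bicubic-resampled to 224 x 224 x 3.
#' Rows run from `f_max_hz` at the top to 0 Hz at the bottom; columns are
#' chronological. A zero signal renders as the uniform minimum color.
#'
#' @inheritParams spectrogram_matrix
#' @param size output image side.
#' @param palette colormap name passed to [grDevices::hcl.colors()].
#' @return object of class `spectrogram_image`: `pixels`
#'   (size x size x 3 in [0, 1]), `f_max_hz`, `window_s`, `overlap`.
#' @export
spectrogram_image <- function(x, rate_hz, f_max_hz, window_s = 4,
                              overlap = 0.75, size = 224, palette = "Viridis") {
  sp <- spectrogram_matrix(x, rate_hz, f_max_hz, window_s, overlap)
  logm <- log10(sp$mag + 1e-8)
  r <- range(logm)
  norm <- if (r[1] == r[2]) matrix(0, nrow(logm), ncol(logm)) else
    (logm - r[1]) / (r[2] - r[1])
  cols <- hcl.colors(256, palette)
  rgb <- col2rgb(cols) / 255
  idx <- matrix(pmin(floor(norm * 255) + 1L, 256L), nrow(norm), ncol(norm))
  # flip so high frequency is at the top row
  idx <- idx[nrow(idx):1, , drop = FALSE]
  pix <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    chan <- matrix(rgb[ch, idx], nrow(idx), ncol(idx))
    pix[, , ch] <- clip01(resize_bicubic(chan, size, size))
  }
  structure(list(pixels = pix, f_max_hz = f_max_hz, window_s = window_s,
                 overlap = overlap),
            class = "spectrogram_image")
}

#' @export
print.spectrogram_image <- function(x, ...) {
  cat(sprintf("<spectrogram_image> %d x %d x 3, 0-%g Hz, %g s windows\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$f_max_hz, x$window_s))
  invisible(x)
}
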