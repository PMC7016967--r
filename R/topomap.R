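# Inverse-distance-weighted (power p) interpolation of per-electrode values
# onto an n x n grid over [-1, 1]^2. Exact at electrode locations.
idw_grid <- function(values, xy, grid_n = 32, power = 2) {
  g <- seq(-1, 1, length.out = grid_n)
  gy <- rep(g, times = grid_n)   # y varies fastest: column-major row index = y
  gx <- rep(g, each = grid_n)
  out <- numeric(grid_n * grid_n)
  wsum <- numeric(grid_n * grid_n)
  acc <- numeric(grid_n * grid_n)
  exact <- rep(NA_integer_, grid_n * grid_n)
  for (k in seq_len(nrow(xy))) {
    d2 <- (gx - xy[k, 1])^2 + (gy - xy[k, 2])^2
    hit <- d2 < 1e-12
    exact[hit] <- k
    w <- 1 / pmax(d2, 1e-12)^(power / 2)
    acc <- acc + w * values[k]
    wsum <- wsum + w
  }
  out <- acc / wsum
  out[!is.na(exact)] <- values[exact[!is.na(exact)]]
  # rows = y (top = +1), cols = x
  matrix(out, grid_n, grid_n)[grid_n:1, , drop = FALSE]
}

#' Band-power topographic RGB image
#'
#' Encodes the three band-power vectors (theta, alpha, beta over the 14
#' electrodes) as a single 224 x 224 x 3 head-disc image. Each band's values
#' are scatter-interpolated (inverse-distance weighting, power 2) onto a
#' coarse grid, normalized by that band image's maximum, bicubic-resampled to
#' the output size and placed in its color channel (theta = R, alpha = G,
#' beta = B). The channels are alpha-blended with weights proportional to
#' each band's total power (scaled so the strongest band has weight 1),
#' clipped to [0, 1], and zeroed outside the unit head disc. Scaling all
#' three vectors by a common positive constant leaves the image unchanged.
#'
#' @param psd_theta,psd_alpha,psd_beta non-negative per-channel band powers,
#'   one value per montage electrode; not all zero.
#' @param montage data.frame of electrode positions, see [eeg_montage()].
#' @param grid_n coarse interpolation grid side.
#' @param size output image side.
#' @return object of class `topomap_image`: `pixels` (size x size x 3 in
#'   [0, 1]), `band_weights`, `montage`.
#' @export
topomap_rgb <- function(psd_theta, psd_alpha, psd_beta,
                        montage = eeg_montage(), grid_n = 32, size = 224) {
  bands <- list(psd_theta, psd_alpha, psd_beta)
  np <- nrow(montage)
  for (b in bands) {
    if (length(b) != np) stopf("band vector length %d != %d electrodes", length(b), np)
    if (any(!is.finite(b)) || any(b < 0)) stopf("band powers must be finite and non-negative")
  }
  tot <- vapply(bands, sum, numeric(1))
  if (all(tot == 0)) stopf("all-zero band powers: topomap normalization undefined")
  weights <- tot / max(tot)
  xy <- as.matrix(montage[, c("x", "y")])
  # head-disc mask at output resolution (pixel centers)
  g <- seq(-1 + 1 / size, 1 - 1 / size, length.out = size)
  mask <- outer(rev(g), g, function(yy, xx) xx^2 + yy^2 <= 1)
  pix <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    img <- idw_grid(bands[[ch]], xy, grid_n = grid_n)
    m <- max(img)
    if (m > 0) img <- img / m else img[] <- 0
    big <- resize_bicubic(img, size, size)
    pix[, , ch] <- clip01(weights[ch] * big) * mask
  }
  structure(list(pixels = pix, band_weights = weights, montage = montage),
            class = "topomap_image")
}

#' @export
print.topomap_image <- function(x, ...) {
  cat(sprintf("<topomap_image> %d x %d x 3, band weights R/G/B = %.3f/%.3f/%.3f\n",
              dim(x$pixels)[1], dim(x$pixels)[2],
              x$band_weights[1], x$band_weights[2], x$band_weights[3]))
  invisible(x)
}

#' Windowed topographic image sequence
#'
#' Splits an EEG trial into contiguous non-overlapping windows
#' (`windows_per_second * duration` of them, which must be a whole number)
#' and renders one topographic RGB image per window, in chronological order.
#' One image per second suits attention-length trials; 30 images per second
#' gives 60 images for a 2-s incident. Band powers for sub-second windows use
#' a zero-padded periodogram.
#'
#' @param eeg [signal_stream()] or samples-by-channels matrix (canonical
#'   14-channel montage).
#' @param windows_per_second windows per second of data.
#' @param rate_hz sampling rate if `eeg` is a matrix.
#' @param ... passed to [topomap_rgb()].
#' @return list of `topomap_image` objects.
#' @export
topomap_sequence <- function(eeg, windows_per_second = 1, rate_hz = NULL, ...) {
  if (inherits(eeg, "signal_stream")) {
    eeg <- check_eeg_montage(eeg)
    rate_hz <- eeg$rate_hz
    m <- eeg$samples
  } else m <- as.matrix(eeg)
  if (is.null(rate_hz)) stopf("rate_hz required for matrix input")
  n <- nrow(m)
  dur <- n / rate_hz
  k <- windows_per_second * dur
  if (abs(k - round(k)) > 1e-6 || k < 1) {
    stopf("windows_per_second * duration = %g must be a positive integer", k)
  }
  k <- round(k)
  bounds <- round(seq(0, n, length.out = k + 1))
  out <- vector("list", k)
  for (w in seq_len(k)) {
    idx <- (bounds[w] + 1):bounds[w + 1]
    if (length(idx) < 2) stopf("window %d has fewer than 2 samples", w)
    seg <- m[idx, , drop = FALSE]
    win_s <- if (length(idx) >= rate_hz) 1 else NULL
    th <- band_psd(seg, "theta", rate_hz = rate_hz, window_s = win_s)
    al <- band_psd(seg, "alpha", rate_hz = rate_hz, window_s = win_s)
    be <- band_psd(seg, "beta", rate_hz = rate_hz, window_s = win_s)
    out[[w]] <- topomap_rgb(th, al, be, ...)
  }
  out
}
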