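# Catmull-Rom bicubic resampling (a = -0.5), half-pixel centers, clamped
# edges. Separable: out = Rrow %*% mat %*% t(Rcol). Reproduces linear ramps
# exactly away from the clamped border.
bicubic_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- floor(src)
  t <- src - i0
  w <- cbind(-0.5 * t + t^2 - 0.5 * t^3,
             1 - 2.5 * t^2 + 1.5 * t^3,
             0.5 * t + 2 * t^2 - 1.5 * t^3,
             -0.5 * t^2 + 0.5 * t^3)
  for (k in 1:4) {
    idx <- pmin(pmax(i0 + (k - 2L), 0L), n_in - 1L) + 1L
    W[cbind(seq_len(n_out), idx)] <- W[cbind(seq_len(n_out), idx)] + w[, k]
  }
  W
}

resize_bicubic <- function(mat, out_h, out_w) {
  Rr <- bicubic_weights(nrow(mat), out_h)
  Rc <- bicubic_weights(ncol(mat), out_w)
  Rr %*% mat %*% t(Rc)
}

#' Resize an RGB image to the embedding input shape
#'
#' Bicubic (Catmull-Rom) resampling of each color channel to 224 x 224,
#' with values clipped to [0, 1]. Images are floats in [0, 1] at this
#' boundary; 8-bit conversion happens only at PNG I/O.
#'
#' @param image numeric `h x w x 3` array in [0, 1].
#' @param size output side length (default 224).
#' @return `size x size x 3` array in [0, 1].
#' @export
resize_to_input <- function(image, size = 224) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) {
    stopf("expected an RGB (h x w x 3) image, got dims [%s]",
          paste(d, collapse = ", "))
  }
  if (d[1] < 1 || d[2] < 1) stopf("empty image")
  out <- array(0, c(size, size, 3))
  for (ch in 1:3) out[, , ch] <- clip01(resize_bicubic(image[, , ch], size, size))
  out
}

#' Write an RGB image array as an 8-bit PNG
#'
#' @param image `h x w x 3` array in [0, 1], or a topomap/spectrogram image
#'   object with a `pixels` element.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_image_png <- function(image, path) {
  if (is.list(image) && !is.null(image$pixels)) image <- image$pixels
  png::writePNG(clip01(image), path)
  invisible(path)
}
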