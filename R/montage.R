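#' Canonical 14-electrode montage
#'
#' The consumer-headset montage used throughout: 14 electrodes of the
#' international 10-20 system sampled at 128 Hz. [eeg_channel_names()] gives
#' the canonical ordering (also the ordering of channel-pair features);
#' [eeg_montage()] adds 2-D head-disc coordinates obtained by
#' azimuthal-equidistant projection of the standard 10-20 spherical positions,
#' rescaled so the outermost electrode lies at radius 0.95 of the unit disc.
#'
#' @return `eeg_channel_names()`: character vector of length 14.
#'   `eeg_montage()`: data.frame with columns `channel`, `x`, `y`.
#' @examples
#' eeg_montage()
#' @export
eeg_channel_names <- function() {
  c("AF3", "AF4", "F3", "F4", "F7", "F8", "FC5", "FC6",
    "T7", "T8", "P7", "P8", "O1", "O2")
}

#' @rdname eeg_channel_names
#' @export
eeg_montage <- function() {
  # azimuthal-equidistant projection of standard 10-20 positions (frozen)
  raw <- rbind(
    AF3 = c(-0.3383, 0.7713),
    AF4 = c(0.3507, 0.7633),
    F3  = c(-0.4582, 0.4844),
    F4  = c(0.4716, 0.4940),
    F7  = c(-0.9311, 0.5628),
    F8  = c(0.9303, 0.5657),
    FC5 = c(-0.7872, 0.1901),
    FC6 = c(0.7911, 0.1983),
    T7  = c(-1.0503, -0.1999),
    T8  = c(1.0534, -0.1860),
    P7  = c(-0.7129, -0.7230),
    P8  = c(0.7181, -0.7182),
    O1  = c(-0.2408, -0.9207),
    O2  = c(0.2447, -0.9198)
  )
  r <- sqrt(rowSums(raw^2))
  scl <- 0.95 / max(r)
  data.frame(channel = rownames(raw),
             x = raw[, 1] * scl, y = raw[, 2] * scl,
             row.names = NULL, stringsAsFactors = FALSE)
}
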