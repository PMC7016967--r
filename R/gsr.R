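#' Skin-conductance-response peak features
#'
#' Counts phasic SCR peaks in a low-pass-filtered skin-conductance trace and
#' reports the mean of their absolute heights. A peak's height is measured
#' from the preceding local trough (onset), which separates the phasic SCR
#' from the tonic skin-conductance level; peaks smaller than `min_height`
#' are ignored. A trace without qualifying peaks returns `(0, 0)`.
#'
#' @param x numeric skin-conductance signal (already low-pass filtered, e.g.
#'   via [moving_average()]).
#' @param rate_hz sampling rate in Hz.
#' @param min_height minimum onset-to-peak amplitude (same units as `x`).
#' @return named numeric vector `c(npeaks, mean_height)`.
#' @export
gsr_peak_features <- function(x, rate_hz, min_height = 0.01) {
  n <- length(x)
  if (n < 3) return(c(npeaks = 0, mean_height = 0))
  dx <- diff(x)
  maxima <- which(dx[-length(dx)] > 0 & dx[-1] <= 0) + 1L
  minima <- which(dx[-length(dx)] < 0 & dx[-1] >= 0) + 1L
  if (length(maxima) == 0) return(c(npeaks = 0, mean_height = 0))
  heights <- vapply(maxima, function(i) {
    prev_min <- minima[minima < i]
    base <- if (length(prev_min) > 0) x[max(prev_min)] else x[1]
    x[i] - base
  }, numeric(1))
  keep <- abs(heights) >= min_height
  if (!any(keep)) return(c(npeaks = 0, mean_height = 0))
  c(npeaks = sum(keep), mean_height = mean(abs(heights[keep])))
}
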