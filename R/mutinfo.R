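#' Plug-in mutual information and conditional entropy
#'
#' Histogram plug-in estimator of the mutual information
#' \eqn{I(X;Y) = \sum_{x,y} p(x,y) \log_2 p(x,y)/(p(x)p(y))} between two
#' signals, with equal-width bins per variable over each variable's observed
#' range. The conditional entropy follows from the identity
#' \eqn{I(X;Y) = H(Y) - H(Y|X)}, which holds exactly for the plug-in
#' quantities (all in bits; \eqn{0 \log 0 := 0}).
#'
#' @param x,y numeric vectors of equal length (at least `2 * bin_count`).
#' @param bin_count number of bins per variable.
#' @return object of class `mi_estimate`: `I_xy`, `H_y`, `H_y_given_x`
#'   (bits), `bin_count`, `joint_hist` (bin_count x bin_count counts).
#' @examples
#' est <- mutual_information(rnorm(1000), rnorm(1000), 16)
#' est$I_xy
#' @export
mutual_information <- function(x, y, bin_count = 16) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 2 * bin_count) {
    stopf("need at least 2 * bin_count = %d samples, got %d", 2 * bin_count, n)
  }
  bx <- bin_index(x, bin_count)
  by <- bin_index(y, bin_count)
  counts <- tabulate((bx - 1L) * bin_count + by, nbins = bin_count^2)
  joint <- matrix(counts, nrow = bin_count, ncol = bin_count, byrow = TRUE)
  p <- joint / n
  H_xy <- plugin_entropy(p)
  H_x <- plugin_entropy(rowSums(p))
  H_y <- plugin_entropy(colSums(p))
  I <- H_x + H_y - H_xy
  structure(list(I_xy = I, H_y = H_y, H_y_given_x = H_xy - H_x,
                 bin_count = bin_count, joint_hist = joint),
            class = "mi_estimate")
}

# equal-width bins over the observed range; constant input -> single bin
bin_index <- function(v, bins) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  i <- floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin(i, bins)
}

plugin_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate> I(X;Y) = %.4f bits, H(Y) = %.4f, H(Y|X) = %.4f (%d bins)\n",
              x$I_xy, x$H_y, x$H_y_given_x, x$bin_count))
  invisible(x)
}

#' Conditional-entropy features for all channel pairs
#'
#' One feature per unordered electrode pair: the conditional entropy
#' \eqn{H(Y|X)} from the plug-in estimator, where for the pair `(i, j)`
#' (`i` before `j` in the canonical electrode ordering) `X` is channel `i`
#' and `Y` is channel `j`. The 14-channel montage yields `choose(14, 2) = 91`
#' features, ordered lexicographically by the canonical electrode list.
#'
#' @param eeg numeric samples-by-channels matrix, or a [signal_stream()]
#'   (reordered to the canonical montage).
#' @param bin_count histogram bins per channel.
#' @return a [feature_block()] with names `ce_<X>_<Y>`.
#' @export
conditional_entropy_vector <- function(eeg, bin_count = 16) {
  if (inherits(eeg, "signal_stream")) {
    eeg <- check_eeg_montage(eeg)
    m <- eeg$samples
  } else m <- as.matrix(eeg)
  nc <- ncol(m)
  if (nc < 2) stopf("need at least 2 channels, got %d", nc)
  chans <- colnames(m)
  if (is.null(chans)) chans <- paste0("ch", seq_len(nc))
  prs <- combn(nc, 2)
  vals <- numeric(ncol(prs))
  nms <- character(ncol(prs))
  for (k in seq_len(ncol(prs))) {
    i <- prs[1, k]; j <- prs[2, k]
    est <- mutual_information(m[, i], m[, j], bin_count)
    vals[k] <- est$H_y_given_x
    nms[k] <- paste0("ce_", chans[i], "_", chans[j])
  }
  feature_block("eeg", "entropy", vals, nms)
}
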