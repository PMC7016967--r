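# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# plug-in mutual information by explicit double sum over a joint count table
mi_brute_force <- function(joint) {
  n <- sum(joint)
  p <- joint / n
  px <- rowSums(p)
  py <- colSums(p)
  acc <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) acc <- acc + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  acc
}

# AUC by exhaustive concordant-pair counting (ties count 1/2)
auc_pair_count <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels <= 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# linear-interpolation (type 7) percentile, written out directly
p95_order_statistic <- function(v, p = 0.95) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
}

# bilaterally symmetric single-frame fixture around the template
symmetric_frame <- function() {
  list(points = face_landmark_template(), face_w = 200, face_h = 200)
}

make_sine_eeg <- function(freq, duration_s = 10, rate = 128, channels = 14) {
  t <- (seq_len(duration_s * rate) - 1) / rate
  matrix(rep(sin(2 * pi * freq * t), channels), ncol = channels)
}

write_tmp_config <- function(dir, generator) {
  path <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(generator = generator), path, auto_unbox = TRUE)
  path
}
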