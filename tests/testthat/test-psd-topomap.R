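test_that("band PSD concentrates power in the right band", {
  rate <- 128
  m <- make_sine_eeg(10, duration_s = 8, channels = 1)
  alpha <- band_psd(m, "alpha", rate_hz = rate)
  theta <- band_psd(m, "theta", rate_hz = rate)
  beta <- band_psd(m, "beta", rate_hz = rate)
  expect_gt(alpha / max(theta, 1e-15), 100)
  expect_gt(alpha / max(beta, 1e-15), 100)

  expect_equal(band_psd(matrix(0, 1024, 3), "alpha", rate_hz = rate),
               rep(0, 3))
  expect_error(band_psd(m, c(10, 70), rate_hz = rate), "Nyquist")
})

test_that("white-noise in-band power is proportional to bandwidth", {
  set.seed(2)
  x <- matrix(rnorm(10000), ncol = 1)
  bands <- eeg_bands()
  integrated <- vapply(seq_len(3), function(b) {
    band_psd(x, c(bands$lo_hz[b], bands$hi_hz[b]), rate_hz = 128) *
      (bands$hi_hz[b] - bands$lo_hz[b])
  }, numeric(1))
  widths <- bands$hi_hz - bands$lo_hz
  ratio <- integrated / widths
  expect_lt(max(ratio) / min(ratio), 1.2)
})

test_that("topomap colors follow the band vectors", {
  v <- runif(14, 0.5, 1)
  # zero beta vector -> blue channel identically 0
  tm <- topomap_rgb(v, v * 2, rep(0, 14))
  expect_true(all(tm$pixels[, , 3] == 0))
  expect_gt(max(tm$pixels[, , 2]), 0)
  # equal vectors in all bands -> identical channels
  tm2 <- topomap_rgb(v, v, v)
  expect_equal(tm2$pixels[, , 1], tm2$pixels[, , 2])
  expect_equal(tm2$pixels[, , 2], tm2$pixels[, , 3])
  expect_error(topomap_rgb(rep(0, 14), rep(0, 14), rep(0, 14)), "all-zero")
})

test_that("a single hot electrode pins the red maximum near that electrode", {
  mont <- eeg_montage()
  for (hot in c(1, 9, 14)) {
    v <- rep(0, 14); v[hot] <- 1
    tm <- topomap_rgb(v, rep(0.5, 14), rep(0.5, 14))
    red <- tm$pixels[, , 1]
    pk <- which(red == max(red), arr.ind = TRUE)[1, ]
    size <- nrow(red)
    # expected pixel: montage (x, y) in [-1, 1], row 1 = y = +1
    ex_col <- (mont$x[hot] + 1) / 2 * size
    ex_row <- (1 - mont$y[hot]) / 2 * size
    expect_lt(sqrt((pk["row"] - ex_row)^2 + (pk["col"] - ex_col)^2), size * 0.06)
  }
})

test_that("topomap is deterministic and invariant to common scaling", {
  set.seed(4)
  th <- runif(14); al <- runif(14); be <- runif(14)
  a <- topomap_rgb(th, al, be)
  b <- topomap_rgb(th, al, be)
  expect_identical(a$pixels, b$pixels)
  c <- topomap_rgb(th * 7.3, al * 7.3, be * 7.3)
  expect_equal(a$pixels, c$pixels, tolerance = 1e-12)
  # pixels outside the head disc are zero
  size <- dim(a$pixels)[1]
  g <- seq(-1 + 1 / size, 1 - 1 / size, length.out = size)
  outside <- outer(rev(g), g, function(yy, xx) xx^2 + yy^2 > 1)
  for (ch in 1:3) expect_true(all(a$pixels[, , ch][outside] == 0))
})

test_that("windowed topomap sequences have one image per window", {
  set.seed(6)
  e35 <- matrix(rnorm(128 * 35 * 14), ncol = 14)
  expect_length(topomap_sequence(e35, 1, rate_hz = 128, grid_n = 8, size = 32), 35)
  e2 <- matrix(rnorm(128 * 2 * 14), ncol = 14)
  expect_length(topomap_sequence(e2, 30, rate_hz = 128, grid_n = 8, size = 32), 60)
  # a single 1-s window equals the whole-trial map
  e1 <- matrix(abs(rnorm(128 * 14)) + 0.1, ncol = 14)
  seq1 <- topomap_sequence(e1, 1, rate_hz = 128)
  th <- band_psd(e1, "theta", rate_hz = 128)
  al <- band_psd(e1, "alpha", rate_hz = 128)
  be <- band_psd(e1, "beta", rate_hz = 128)
  expect_equal(seq1[[1]]$pixels, topomap_rgb(th, al, be)$pixels)
  expect_error(topomap_sequence(e1, 0.3, rate_hz = 128), "positive integer")
})
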