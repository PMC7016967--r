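test_that("the canonical spec list has 30 features and valid indices", {
  specs <- geometric_feature_specs()
  expect_equal(nrow(specs), 30)
  expect_equal(sum(specs$kind == "distance"), 22)
  expect_equal(sum(specs$kind == "angle"), 8)
  groups <- face_landmark_groups()
  for (g in unlist(specs[, c("a", "b")], use.names = FALSE)) {
    expect_true(g %in% names(groups))
  }
  expect_true(all(unlist(groups) >= 1 & unlist(groups) <= 49))
})

test_that("a symmetric face gives equal left/right homologous features", {
  fr <- symmetric_frame()
  f <- geometric_features(fr$points, fr$face_w, fr$face_h)[1, ]
  specs <- geometric_feature_specs()
  homologs <- list(c("lbrow_leye", "rbrow_reye"), c("leye_width", "reye_width"),
                   c("leye_height", "reye_height"), c("nose_lmouth", "nose_rmouth"),
                   c("lbrow_nosetop", "rbrow_nosetop"), c("leye_nose", "reye_nose"),
                   c("lmouth_leye", "rmouth_reye"), c("lmouth_corner", "rmouth_corner"),
                   c("lbrow_bend", "rbrow_bend"), c("leye_open_angle", "reye_open_angle"))
  for (h in homologs) {
    i <- specs$id[specs$name == h[1]]
    j <- specs$id[specs$name == h[2]]
    expect_equal(unname(f[i]), unname(f[j]), tolerance = 1e-12)
  }
})

test_that("features are invariant to translation and uniform scaling", {
  fr <- symmetric_frame()
  base <- geometric_features(fr$points, fr$face_w, fr$face_h)
  scaled <- geometric_features(fr$points * 2, fr$face_w * 2, fr$face_h * 2)
  expect_equal(base, scaled, tolerance = 1e-12)
  shifted <- geometric_features(fr$points + 37, fr$face_w, fr$face_h)
  expect_equal(base, shifted, tolerance = 1e-12)
  # angles additionally rotation-invariant
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- geometric_features(fr$points %*% R, fr$face_w, fr$face_h)
  specs <- geometric_feature_specs()
  ang <- specs$id[specs$kind == "angle"]
  expect_equal(base[1, ang], rot[1, ang], tolerance = 1e-12)
})

test_that("a worked distance matches direct Euclidean computation", {
  fr <- symmetric_frame()
  f <- geometric_features(fr$points, fr$face_w, fr$face_h)[1, ]
  g <- face_landmark_groups()
  brow <- colMeans(fr$points[g$left_brow, ])
  eye <- colMeans(fr$points[g$left_eye, ])
  manual <- sqrt(sum((brow - eye)^2)) / fr$face_h
  expect_equal(unname(f["geo01"]), manual, tolerance = 1e-12)
})

test_that("degenerate angles warn and return 0", {
  fr <- symmetric_frame()
  pts <- fr$points
  g <- face_landmark_groups()
  # collapse both mouth corners onto the nose tip: angle at the tip degenerates
  pts[c(g$mouth_left, g$mouth_right), ] <-
    rep(pts[g$nose_tip, ], each = 2)
  expect_warning(f <- geometric_features(pts, 200, 200), "degenerate")
  expect_equal(unname(f[1, "geo23"]), 0)
})

test_that("trial aggregation matches the order-statistic oracle", {
  m <- matrix(1:100, ncol = 1)
  agg <- aggregate_trial(cbind(m, m * 2))
  expect_length(agg$block, 6)
  expect_equal(unname(agg$p95_vec[1]), 95.05)
  expect_equal(unname(agg$p95_vec[1]), p95_order_statistic(1:100))

  gm <- geometric_features(gen_landmarks("high", 20, seed = 16))
  expect_length(aggregate_trial(gm)$block, 90)
  emb <- matrix(rnorm(5 * 4096), 5)
  expect_length(aggregate_trial(emb)$block, 12288)

  same <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4)
  a <- aggregate_trial(same)
  expect_equal(unname(a$std_vec), c(0, 0, 0))
  expect_equal(unname(a$mean_vec), unname(a$p95_vec))
  expect_error(aggregate_trial(matrix(1:5, nrow = 1)), "2 frames")
})

test_that("aggregation commutes with column permutation and p95 is monotone", {
  set.seed(17)
  m <- matrix(rnorm(40), 10, 4)
  perm <- c(3, 1, 4, 2)
  a <- aggregate_trial(m)
  b <- aggregate_trial(m[, perm])
  expect_equal(unname(b$mean_vec), unname(a$mean_vec[perm]))
  expect_equal(unname(b$p95_vec), unname(a$p95_vec[perm]))
  expect_equal(unname(b$std_vec), unname(a$std_vec[perm]))
  # adding a row of columnwise maxima never decreases p95
  m2 <- rbind(m, apply(m, 2, max))
  expect_true(all(aggregate_trial(m2)$p95_vec >= a$p95_vec - 1e-12))
})

test_that("embedding sequences preserve frame order and shape", {
  emb <- image_embedder("stub", seed = 3)
  img1 <- array(0.2, c(224, 224, 3))
  img2 <- array(0.8, c(224, 224, 3))
  M <- face_embedding_sequence(list(img1, img2, img1), emb)
  expect_equal(dim(M), c(3, 4096))
  expect_identical(M[1, ], M[3, ])
  expect_gt(sqrt(sum((M[1, ] - M[2, ])^2)), 0)
  bad <- image_embedder("stub", seed = 3)
  bad$embed_fn <- function(img) rep(1, 10)
  expect_error(face_embedding_sequence(list(img1), bad), "4096")
})
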