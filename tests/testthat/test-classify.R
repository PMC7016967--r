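test_that("normalization maps fitted ranges to [-1, 1] without clipping", {
  X <- cbind(a = c(0, 5, 10), b = c(7, 7, 7))
  nf <- normalize_fit(X)
  out <- normalize_apply(X, nf)
  expect_equal(out[, 1], c(-1, 0, 1))
  expect_equal(out[, 2], c(0, 0, 0))  # constant column -> 0
  # train-only scope: unseen test values exceed 1
  tr <- matrix(c(0, 1, 2), ncol = 1)
  te <- matrix(5, 1, 1)
  expect_equal(normalize_apply(te, normalize_fit(tr))[1, 1], 4)
  expect_error(normalize_fit(matrix(numeric(0), 0, 0)), "empty")
})

test_that("PCA reduction matches an independent eigendecomposition", {
  set.seed(19)
  X <- matrix(rnorm(200 * 6), 200, 6) %*% diag(c(5, 3, 2, 1, 0.5, 0.1))
  pr <- pca_reduce(X, 6)
  ev <- sort(eigen(stats::cov(X), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(pr$fit$explained, ev, tolerance = 1e-8)
  # full-rank k = p reconstructs exactly
  recon <- pr$scores %*% t(pr$fit$rotation) +
    matrix(pr$fit$center, nrow(X), 6, byrow = TRUE)
  expect_equal(recon, X, tolerance = 1e-9)
  # rank-1 data: one component explains everything
  Y <- outer(rnorm(50), c(1, 2, 3))
  pf <- pca_fit(Y, 1)
  expect_equal(pf$explained_frac[1], 1, tolerance = 1e-12)
  expect_error(pca_fit(X, 7), "out of range")
})

test_that("the triangular basis activation is exact", {
  expect_equal(tribas(c(0, 1, -1, 2, -2, 0.25)), c(1, 0, 0, 0, 0, 0.75))
})

test_that("ELM is deterministic, interpolates when over-parameterized, and predicts sanely", {
  set.seed(20)
  X <- matrix(runif(40 * 5, -1, 1), 40, 5)
  y <- ifelse(X[, 1] + 0.5 * X[, 2] > 0, 1, -1)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  m1 <- elm_train(X, y, n_hidden = 170, seed = 4)
  m2 <- elm_train(X, y, n_hidden = 170, seed = 4)
  expect_identical(m1$output_weights, m2$output_weights)
  pred <- elm_predict(m1, X)
  expect_equal(mean(pred$label == y), 1)
  # permuting rows permutes outputs identically
  perm <- sample(nrow(X))
  expect_equal(elm_predict(m1, X[perm, ])$score, pred$score[perm])
  # tie rule: score 0 is positive
  m0 <- m1; m0$output_weights[] <- 0
  expect_true(all(elm_predict(m0, X)$label == 1))
  expect_error(elm_train(X, rep(1, 40)), "one class")
  expect_error(elm_predict(m1, X[, 1:3]), "columns")
})

test_that("ELM training accuracy is non-decreasing in hidden width", {
  set.seed(21)
  X <- matrix(runif(60 * 4, -1, 1), 60, 4)
  y <- ifelse(X[, 1] * X[, 2] > 0, 1, -1)
  acc <- vapply(c(10, 50, 170), function(h) {
    m <- elm_train(X, y, n_hidden = h, seed = 2)
    mean(elm_predict(m, X)$label == y)
  }, numeric(1))
  expect_true(all(diff(acc) >= -1e-12))
})

test_that("AUC equals the brute-force pair count on random instances", {
  expect_equal(auc(c(1, 2, 3, 10, 11), c(-1, -1, -1, 1, 1)), 1)
  expect_equal(auc(rep(1, 6), c(1, 1, 1, -1, -1, -1)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), "one class")
  set.seed(22)
  for (i in 1:200) {
    n <- sample(6:20, 1)
    sc <- sample(1:8, n, replace = TRUE)  # heavy ties
    lb <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(lb)) < 2) lb[1] <- -lb[1]
    expect_equal(auc(sc, lb), auc_pair_count(sc, lb), tolerance = 1e-12)
  }
})

test_that("paired t-test and ANOVA match closed-form references", {
  a <- c(1, 2, 3, 4, 5)
  expect_warning(r0 <- paired_ttest(a, a), "zero-variance")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # textbook paired sample: d = (2, 2, 3, 1, 2), mean 2, sd sqrt(0.5)
  b <- a - c(2, 2, 3, 1, 2)
  r <- paired_ttest(a, b)
  d <- c(2, 2, 3, 1, 2)
  t_manual <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(r$t, t_manual, tolerance = 1e-6)
  expect_equal(r$p, 2 * stats::pt(-abs(t_manual), 4), tolerance = 1e-6)

  g <- list(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7))
  res <- anova_oneway(g)
  ref <- summary(stats::aov(y ~ f, data.frame(y = unlist(g),
                                              f = factor(rep(1:3, each = 3)))))[[1]]
  expect_equal(res$F, ref$`F value`[1], tolerance = 1e-9)
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
  expect_error(anova_oneway(list(1:3)), "2 groups")
})

test_that("equal-mean groups give F near 1 on average", {
  set.seed(23)
  fs <- replicate(500, anova_oneway(list(rnorm(30), rnorm(30), rnorm(30)))$F)
  # E[F] = df2/(df2-2) = 87/85; se of the mean over 500 replicates
  expect_lt(abs(mean(fs) - 87 / 85), 3 * sd(fs) / sqrt(500))
})

test_that("LOSO folds and sizes follow the subject structure", {
  subj <- rep(sprintf("S%02d", 1:12), each = 35)
  folds <- loso_folds(subj)
  expect_length(folds, 12)
  expect_true(all(vapply(folds, function(f) length(f$train), numeric(1)) == 385))
  expect_true(all(vapply(folds, function(f) length(f$test), numeric(1)) == 35))

  set.seed(24)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c(-1, 1), 20)
  cv <- loso_cv(X, y, rep(c("A", "B"), each = 20), n_components = 4, n_hidden = 20)
  expect_equal(nrow(cv$per_subject), 2)
  expect_error(loso_cv(X, y, rep("A", 40)), "2 subjects")
})

test_that("LOSO results are invariant to trial order within subjects", {
  set.seed(25)
  n <- 60
  subj <- rep(c("A", "B", "C"), each = 20)
  X <- matrix(rnorm(n * 8), n, 8)
  y <- rep(c(-1, 1), 30)
  cv1 <- loso_cv(X, y, subj, n_components = 5, n_hidden = 30, seed = 1)
  perm <- unlist(lapply(split(seq_len(n), subj), sample))
  cv2 <- loso_cv(X[perm, ], y[perm], subj[perm], n_components = 5, n_hidden = 30, seed = 1)
  expect_equal(cv1$per_subject$accuracy, cv2$per_subject$accuracy, tolerance = 1e-9)
})
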