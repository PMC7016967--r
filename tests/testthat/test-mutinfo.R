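test_that("identical signals give H(Y|X) = 0 and I = H(Y)", {
  set.seed(1)
  x <- runif(2000)
  est <- mutual_information(x, x, 16)
  expect_lt(abs(est$H_y_given_x), 1e-9)
  expect_equal(est$I_xy, est$H_y, tolerance = 1e-12)
})

test_that("2-bin diagonal joint distribution gives exactly 1 bit", {
  # p(x,y) = [[0.5, 0], [0, 0.5]]: closed form I = 1 bit, H(Y|X) = 0
  x <- rep(c(0, 1), each = 50)
  est <- mutual_information(x, x, 2)
  expect_equal(est$I_xy, 1, tolerance = 1e-12)
  expect_equal(est$H_y, 1, tolerance = 1e-12)
  expect_lt(abs(est$H_y_given_x), 1e-12)
})

test_that("estimator matches the brute-force double sum on the same histogram", {
  set.seed(7)
  for (bins in c(4, 8, 16)) {
    x <- rnorm(3000)
    y <- 0.5 * x + rnorm(3000)
    est <- mutual_information(x, y, bins)
    expect_equal(est$I_xy, mi_brute_force(est$joint_hist), tolerance = 1e-12)
  }
})

test_that("the entropy identity and symmetry hold for every computed pair", {
  set.seed(11)
  for (rep in 1:20) {
    x <- rnorm(600)
    y <- rnorm(600) + 0.3 * x
    a <- mutual_information(x, y, 16)
    b <- mutual_information(y, x, 16)
    expect_lt(abs(a$H_y_given_x - (a$H_y - a$I_xy)), 1e-9)
    expect_gt(a$I_xy, -1e-9)
    expect_lt(a$H_y_given_x, a$H_y + 1e-9)
    expect_lt(abs(a$I_xy - b$I_xy), 1e-9)
  }
})

test_that("MI against permuted copies stays within the plug-in bias bound", {
  set.seed(3)
  n <- 10000; bins <- 16
  x <- runif(n)
  y <- runif(n)
  vals <- replicate(100, mutual_information(x, sample(y), bins)$I_xy)
  bound <- 3 * bins^2 / (2 * n * log(2))
  expect_lt(mean(vals), bound)
})

test_that("constant input is handled without log(0)", {
  est <- mutual_information(rep(1, 100), rnorm(100), 16)
  expect_equal(est$I_xy, 0)
  est2 <- mutual_information(rep(1, 100), rep(2, 100), 16)
  expect_equal(est2$H_y, 0)
})

test_that("channel-pair feature vector has choose(n, 2) entries in canonical order", {
  set.seed(5)
  eeg14 <- matrix(rnorm(512 * 14), ncol = 14,
                  dimnames = list(NULL, eeg_channel_names()))
  fb <- conditional_entropy_vector(eeg14)
  expect_s3_class(fb, "feature_block")
  expect_length(fb$values, 91)
  expect_identical(names(fb$values)[1], "ce_AF3_AF4")
  expect_identical(names(fb$values)[91], "ce_O1_O2")

  fb2 <- conditional_entropy_vector(matrix(rnorm(256 * 2), ncol = 2))
  expect_length(fb2$values, 1)
  expect_error(conditional_entropy_vector(matrix(rnorm(100), ncol = 1)), "2 channels")
})

test_that("identical channels give all-zero conditional entropies", {
  ch <- rnorm(512)
  eeg <- matrix(rep(ch, 4), ncol = 4)
  fb <- conditional_entropy_vector(eeg)
  expect_true(all(abs(fb$values) < 1e-9))
})
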