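#' Feature normalization to [-1, 1]
#'
#' Per-column affine map sending the fitted minimum to -1 and maximum to +1.
#' `normalize_fit()` learns the ranges; `normalize_apply()` applies them
#' (values outside the fitted range map outside [-1, 1]; there is no
#' clipping). Constant columns map to 0. Fitting on the pooled data
#' reproduces the across-subject normalization convention; fitting on the
#' training fold only is the leakage-safe alternative (see [loso_cv()]).
#'
#' @param X numeric matrix, rows = trials.
#' @param fit a fit returned by `normalize_fit()`.
#' @return `normalize_fit()`: list with `min`, `max` per column.
#'   `normalize_apply()`: matrix of the same shape as `X`.
#' @export
normalize_fit <- function(X) {
  X <- as.matrix(X)
  if (length(X) == 0) stopf("empty feature matrix")
  list(min = apply(X, 2, min), max = apply(X, 2, max))
}

#' @rdname normalize_fit
#' @export
normalize_apply <- function(X, fit) {
  X <- as.matrix(X)
  rng <- fit$max - fit$min
  out <- sweep(X, 2, fit$min)
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/") * 2 - 1
  out[, rng == 0] <- 0
  out
}

#' PCA dimensionality reduction
#'
#' Projects feature rows onto the top-`k` principal axes of the fitted data
#' (components ordered by decreasing explained variance). `pca_fit()` centers
#' and decomposes; `pca_apply()` projects new rows with the fitted basis.
#'
#' @param X numeric matrix, rows = observations.
#' @param k number of components; must satisfy
#'   `k <= min(nrow(X) - 1, ncol(X))`.
#' @param fit a fit from `pca_fit()`.
#' @return `pca_fit()`: list with `rotation` (p x k), `center`, `explained`
#'   (component variances) and `explained_frac`. `pca_apply()` /
#'   `pca_reduce()`: score matrix with `k` columns (`pca_reduce` returns
#'   `list(scores, fit)`).
#' @export
pca_fit <- function(X, k) {
  X <- as.matrix(X)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (k < 1 || k > kmax) {
    stopf("k = %d out of range: need 1 <= k <= min(rows - 1, cols) = %d", k, kmax)
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  # pin the SVD sign ambiguity (largest-magnitude loading positive) so the
  # projection is invariant to row order
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  pc$rotation <- rot
  list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
       center = pc$center,
       explained = vars[seq_len(k)],
       explained_frac = vars[seq_len(k)] / sum(vars),
       k = k)
}

#' @rdname pca_fit
#' @export
pca_apply <- function(X, fit) {
  sweep(as.matrix(X), 2, fit$center) %*% fit$rotation
}

#' @rdname pca_fit
#' @export
pca_reduce <- function(X, k) {
  fit <- pca_fit(X, k)
  list(scores = pca_apply(X, fit), fit = fit)
}

#' Triangular basis activation
#'
#' `tribas(u) = max(1 - |u|, 0)`.
#'
#' @param u numeric.
#' @return numeric of the same shape.
#' @export
tribas <- function(u) pmax(1 - abs(u), 0)

#' Train an extreme learning machine
#'
#' Single-hidden-layer ELM: input weights and biases are drawn uniformly on
#' [-1, 1] from a recorded seed and frozen; the hidden layer is
#' `H = tribas(X W' + b)` (170 units by default); output weights solve the
#' ridge-regularized least squares `H beta = y` (lambda = 1e-6) via the
#' normal equations, falling back to the Moore-Penrose pseudo-inverse when
#' ill-conditioned. Labels are +1/-1 (+1 = high attention / hazardous by the
#' package's convention).
#'
#' @param X numeric feature matrix (normalize to [-1, 1] first).
#' @param y labels in \{-1, +1\}; both classes must be present.
#' @param n_hidden hidden-layer width.
#' @param seed seed for the frozen random input layer.
#' @param lambda ridge regularization.
#' @return object of class `elm_model`.
#' @export
elm_train <- function(X, y, n_hidden = 170, seed = 1, lambda = 1e-6) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stopf("y must be coded -1/+1")
  if (length(unique(y)) < 2) stopf("degenerate training set: only one class present")
  if (nrow(X) != length(y)) stopf("nrow(X) != length(y)")
  p <- ncol(X)
  wb <- with_seed(seed, {
    list(W = matrix(runif(n_hidden * p, -1, 1), n_hidden, p),
         b = runif(n_hidden, -1, 1))
  })
  H <- elm_hidden(X, wb$W, wb$b)
  A <- crossprod(H) + diag(lambda, n_hidden)
  beta <- tryCatch(solve(A, crossprod(H, y)),
                   error = function(e) MASS::ginv(A) %*% crossprod(H, y))
  structure(list(input_weights = wb$W, biases = wb$b,
                 output_weights = as.numeric(beta),
                 n_hidden = n_hidden, n_features = p,
                 activation = "tribas", seed = seed, lambda = lambda),
            class = "elm_model")
}

elm_hidden <- function(X, W, b) {
  tribas(X %*% t(W) + matrix(b, nrow(X), length(b), byrow = TRUE))
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> %d features -> %d hidden (tribas) -> 1, seed %d\n",
              x$n_features, x$n_hidden, x$seed))
  invisible(x)
}

#' Predict with an ELM
#'
#' Continuous score `H beta` (exposed for AUC) and hard label
#' `sign(score)`, with a score of exactly 0 assigned to the positive class.
#'
#' @param model an `elm_model`.
#' @param X feature matrix with the training columns.
#' @return list with `score` and `label` (+1/-1).
#' @export
elm_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stopf("X has %d columns but the model was trained on %d", ncol(X), model$n_features)
  }
  score <- as.numeric(elm_hidden(X, model$input_weights, model$biases) %*% model$output_weights)
  list(score = score, label = ifelse(score >= 0, 1, -1))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from ranks (equivalently the
#' concordant-pair fraction), with tied scores contributing 1/2.
#'
#' @param scores numeric classifier scores.
#' @param labels +1/-1 (or logical); both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("AUC undefined: only one class present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired two-sided t-test
#'
#' Thin wrapper around [stats::t.test()] reporting the statistic, degrees of
#' freedom and p-value in full. Zero-variance differences are reported as
#' `t = 0, p = 1` with a warning.
#'
#' @param a,b paired numeric vectors of equal length (at least 2).
#' @return list with `t`, `df`, `p`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stopf("need paired vectors of equal length >= 2")
  }
  d <- a - b
  if (sd(d) == 0) {
    warnf("zero-variance differences: p reported as 1")
    return(list(t = 0, df = length(a) - 1L, p = 1))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' One-way ANOVA F statistic
#'
#' Classical equal-variance one-way ANOVA across groups.
#'
#' @param groups list of numeric vectors (at least 2 groups).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stopf("need a list of >= 2 groups")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(res$statistic), df1 = unname(res$parameter[1]),
       df2 = unname(res$parameter[2]), p = res$p.value)
}

#' Leave-one-subject-out split
#'
#' @param subjects vector of subject ids, one per trial.
#' @return named list of folds, each `list(train, test)` index vectors; one
#'   fold per distinct subject.
#' @export
loso_folds <- function(subjects) {
  ids <- unique(subjects)
  out <- lapply(ids, function(s) {
    list(train = which(subjects != s), test = which(subjects == s))
  })
  names(out) <- as.character(ids)
  out
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject: fit the scaler, PCA basis and classifier on all other
#' subjects' trials, then evaluate on the held-out subject. Reports per-fold
#' accuracy (percent) and rank AUC (from continuous scores; `NA` when the
#' held-out subject has a single class), with mean and standard deviation
#' across subjects. `fit_scope = "train_only"` (the default) fits scaler and
#' PCA on the training fold only; `"global"` fits them on the pooled data,
#' reproducing the across-subject normalization convention.
#'
#' @param X numeric feature matrix, rows = trials.
#' @param y labels +1/-1.
#' @param subjects subject id per trial.
#' @param n_components PCA dimensionality (capped at the feasible maximum).
#' @param n_hidden ELM hidden width.
#' @param seed seed for the classifier's frozen random layer.
#' @param fit_scope `"train_only"` or `"global"`.
#' @param classifier `"elm"`, or a `list(train = function(X, y),
#'   predict = function(model, X) -> list(score, label))` for a custom
#'   classifier.
#' @return object of class `cv_result`: `per_subject` data.frame,
#'   `mean_accuracy`, `sd_accuracy`, `mean_auc`, `sd_auc`, `fold_sizes`.
#' @export
loso_cv <- function(X, y, subjects, n_components = 30, n_hidden = 170,
                    seed = 1, fit_scope = c("train_only", "global"),
                    classifier = "elm") {
  fit_scope <- match.arg(fit_scope)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(subjects)) < 2) stopf("LOSO needs at least 2 subjects")
  folds <- loso_folds(subjects)
  acc <- numeric(length(folds))
  aucs <- rep(NA_real_, length(folds))
  ntest <- integer(length(folds))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    fit_rows <- if (fit_scope == "global") seq_len(nrow(X)) else tr
    nf <- normalize_fit(X[fit_rows, , drop = FALSE])
    Xn_tr <- normalize_apply(X[tr, , drop = FALSE], nf)
    Xn_te <- normalize_apply(X[te, , drop = FALSE], nf)
    Xn_fit <- normalize_apply(X[fit_rows, , drop = FALSE], nf)
    k <- min(n_components, nrow(Xn_fit) - 1L, ncol(Xn_fit))
    pf <- pca_fit(Xn_fit, k)
    Ztr <- pca_apply(Xn_tr, pf)
    Zte <- pca_apply(Xn_te, pf)
    if (identical(classifier, "elm")) {
      model <- elm_train(Ztr, y[tr], n_hidden = n_hidden, seed = seed)
      pred <- elm_predict(model, Zte)
    } else {
      model <- classifier$train(Ztr, y[tr])
      pred <- classifier$predict(model, Zte)
    }
    acc[f] <- 100 * mean(pred$label == y[te])
    if (length(unique(y[te])) == 2) aucs[f] <- auc(pred$score, y[te])
    ntest[f] <- length(te)
  }
  per <- data.frame(subject = names(folds), n_test = ntest,
                    accuracy = acc, auc = aucs, stringsAsFactors = FALSE)
  structure(list(per_subject = per,
                 mean_accuracy = mean(acc), sd_accuracy = sd(acc),
                 mean_auc = mean(aucs, na.rm = TRUE),
                 sd_auc = sd(aucs[!is.na(aucs)]),
                 fold_sizes = data.frame(subject = names(folds),
                                         n_train = lengths(lapply(folds, `[[`, "train")),
                                         n_test = ntest)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d subjects: accuracy %.2f +/- %.2f %%, AUC %.3f +/- %.3f\n",
              nrow(x$per_subject), x$mean_accuracy, x$sd_accuracy,
              x$mean_auc, x$sd_auc))
  invisible(x)
}
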