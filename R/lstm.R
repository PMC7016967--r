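#' LSTM classifier specification
#'
#' Two-layer LSTM (200 and 100 units by default) with a logistic readout on
#' the final step of the second layer, trained by stochastic gradient
#' descent with momentum (SGDM). Sequence features are expected to be
#' reduced to 60 dimensions per step (e.g. via [pca_reduce()]) before
#' training. Unstated training details default to: learning rate 0.01,
#' momentum 0.9, 50 epochs, batch size 16, uniform `+-1/sqrt(fan)`
#' initialization with forget-gate bias +1.
#'
#' @param input_dim features per time step.
#' @param layer_sizes hidden widths of the two recurrent layers.
#' @param learning_rate,momentum SGDM hyperparameters.
#' @param epochs,batch_size training schedule.
#' @param seed RNG seed (initialization and shuffling).
#' @return object of class `lstm_spec`.
#' @export
lstm_spec <- function(input_dim = 60, layer_sizes = c(200, 100),
                      learning_rate = 0.01, momentum = 0.9,
                      epochs = 50, batch_size = 16, seed = 1) {
  if (length(layer_sizes) != 2) stopf("exactly two recurrent layers are supported")
  structure(list(input_dim = as.integer(input_dim),
                 layer_sizes = as.integer(layer_sizes),
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "lstm_spec")
}

sigm <- function(x) 1 / (1 + exp(-x))

lstm_init_params <- function(spec) {
  dims <- c(spec$input_dim, spec$layer_sizes)
  layers <- vector("list", 2)
  for (l in 1:2) {
    D <- dims[l]; H <- dims[l + 1]
    r <- 1 / sqrt(D + H)
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias
    layers[[l]] <- list(Wx = matrix(runif(D * 4 * H, -r, r), D, 4 * H),
                        Wh = matrix(runif(H * 4 * H, -r, r), H, 4 * H),
                        b = b)
  }
  H2 <- dims[3]
  list(layers = layers,
       w = runif(H2, -1 / sqrt(H2), 1 / sqrt(H2)),
       b0 = 0)
}

# Forward pass and (optionally) full BPTT for a minibatch.
# X: array (T, B, D); y: +-1 length B (NULL for prediction).
lstm_forward_backward <- function(params, X, y = NULL, grads = TRUE) {
  Tn <- dim(X)[1]; B <- dim(X)[2]
  Hs <- vapply(params$layers, function(l) length(l$b) / 4L, numeric(1))
  h <- lapply(Hs, function(H) matrix(0, B, H))
  cc <- lapply(Hs, function(H) matrix(0, B, H))
  cache <- if (grads) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    xin <- matrix(X[t, , ], B, dim(X)[3])
    step <- vector("list", 2)
    for (l in 1:2) {
      P <- params$layers[[l]]
      H <- Hs[l]
      Z <- xin %*% P$Wx + h[[l]] %*% P$Wh + matrix(P$b, B, 4 * H, byrow = TRUE)
      i <- sigm(Z[, 1:H, drop = FALSE])
      f <- sigm(Z[, (H + 1):(2 * H), drop = FALSE])
      o <- sigm(Z[, (2 * H + 1):(3 * H), drop = FALSE])
      g <- tanh(Z[, (3 * H + 1):(4 * H), drop = FALSE])
      cnew <- f * cc[[l]] + i * g
      tc <- tanh(cnew)
      hnew <- o * tc
      if (grads) {
        step[[l]] <- list(xin = xin, hprev = h[[l]], cprev = cc[[l]],
                          i = i, f = f, o = o, g = g, tc = tc)
      }
      h[[l]] <- hnew
      cc[[l]] <- cnew
      xin <- hnew
    }
    if (grads) cache[[t]] <- step
  }
  scores <- as.numeric(h[[2]] %*% params$w + params$b0)
  if (is.null(y)) return(list(scores = scores))
  m <- -y * scores
  loss <- mean(ifelse(m > 30, m, log1p(exp(m))))  # overflow-safe log(1+e^m)
  if (!grads) return(list(scores = scores, loss = loss))

  ds <- (-y * sigm(m)) / B
  G <- list(layers = lapply(params$layers, function(P)
    list(Wx = P$Wx * 0, Wh = P$Wh * 0, b = P$b * 0)),
    w = colSums(ds * h[[2]]), b0 = sum(ds))
  dh_next <- lapply(Hs, function(H) matrix(0, B, H))
  dc_next <- lapply(Hs, function(H) matrix(0, B, H))
  dh_next[[2]] <- outer(ds, params$w)
  for (t in rev(seq_len(Tn))) {
    dx_above <- NULL
    for (l in 2:1) {
      st <- cache[[t]][[l]]
      P <- params$layers[[l]]
      H <- Hs[l]
      dh <- dh_next[[l]]
      if (l == 1 && !is.null(dx_above)) dh <- dh + dx_above
      dc <- dc_next[[l]] + dh * st$o * (1 - st$tc^2)
      di <- dc * st$g
      df <- dc * st$cprev
      do_ <- dh * st$tc
      dg <- dc * st$i
      dZ <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  do_ * st$o * (1 - st$o),
                  dg * (1 - st$g^2))
      G$layers[[l]]$Wx <- G$layers[[l]]$Wx + crossprod(st$xin, dZ)
      G$layers[[l]]$Wh <- G$layers[[l]]$Wh + crossprod(st$hprev, dZ)
      G$layers[[l]]$b <- G$layers[[l]]$b + colSums(dZ)
      dh_next[[l]] <- dZ %*% t(P$Wh)
      dc_next[[l]] <- dc * st$f
      if (l == 2) dx_above <- dZ %*% t(P$Wx) else dx_above <- NULL
    }
  }
  list(scores = scores, loss = loss, grads = G)
}

seqs_to_array <- function(sequences, spec = NULL) {
  Ts <- vapply(sequences, nrow, numeric(1))
  Ds <- vapply(sequences, ncol, numeric(1))
  if (length(unique(Ts)) != 1) {
    stopf(paste0("ragged sequence lengths (%s): the recurrent trend classifier ",
                 "requires a fixed trial duration so every sequence has the ",
                 "same number of steps"), paste(unique(Ts), collapse = ", "))
  }
  if (length(unique(Ds)) != 1) stopf("sequences have differing feature widths")
  if (!is.null(spec) && Ds[1] != spec$input_dim) {
    stopf("sequence feature width %d does not match the spec's %d per-step features (reduce with PCA first)",
          Ds[1], spec$input_dim)
  }
  X <- array(0, c(Ts[1], length(sequences), Ds[1]))
  for (b in seq_along(sequences)) X[, b, ] <- as.matrix(sequences[[b]])
  X
}

#' Train the LSTM sequence classifier
#'
#' @param sequences list of `T x input_dim` matrices, all with the same `T`
#'   (fixed trial duration).
#' @param y labels +1/-1.
#' @param spec an [lstm_spec()].
#' @param verbose print the loss each epoch.
#' @return object of class `lstm_model` with `params`, `spec`, `loss_trace`,
#'   `final_loss`.
#' @export
lstm_train <- function(sequences, y, spec = lstm_spec(), verbose = FALSE) {
  X_all <- seqs_to_array(sequences, spec)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stopf("y must be coded -1/+1")
  n <- length(sequences)
  with_seed(spec$seed, {
    params <- lstm_init_params(spec)
    vel <- rapply(params, function(p) p * 0, how = "replace")
    trace <- numeric(spec$epochs)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0
      for (start in seq(1, n, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1, n)]
        fb <- lstm_forward_backward(params,
                                    X_all[, idx, , drop = FALSE], y[idx])
        upd <- function(v, g) spec$momentum * v - spec$learning_rate * g
        for (l in 1:2) for (nm in c("Wx", "Wh", "b")) {
          vel$layers[[l]][[nm]] <- upd(vel$layers[[l]][[nm]], fb$grads$layers[[l]][[nm]])
          params$layers[[l]][[nm]] <- params$layers[[l]][[nm]] + vel$layers[[l]][[nm]]
        }
        vel$w <- upd(vel$w, fb$grads$w); params$w <- params$w + vel$w
        vel$b0 <- upd(vel$b0, fb$grads$b0); params$b0 <- params$b0 + vel$b0
        ep_loss <- ep_loss + fb$loss
        nb <- nb + 1
      }
      trace[ep] <- ep_loss / nb
      if (verbose) cat(sprintf("epoch %d: loss %.4f\n", ep, trace[ep]))
    }
    structure(list(params = params, spec = spec, loss_trace = trace,
                   final_loss = trace[spec$epochs]),
              class = "lstm_model")
  })
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf("<lstm_model> %d -> %s -> 1, final loss %.4f\n",
              x$spec$input_dim, paste(x$spec$layer_sizes, collapse = "+"),
              x$final_loss))
  invisible(x)
}

#' Predict with a trained LSTM
#'
#' @param model an `lstm_model`.
#' @param sequences list of `T x input_dim` matrices.
#' @return list with `score` and `label` (+1/-1; score 0 is positive).
#' @export
lstm_predict <- function(model, sequences) {
  X <- seqs_to_array(sequences, model$spec)
  sc <- lstm_forward_backward(model$params, X, y = NULL)$scores
  list(score = sc, label = ifelse(sc >= 0, 1, -1))
}
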