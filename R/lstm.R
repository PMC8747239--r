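# The sequence model: sliding-window construction over gait cycles, a
# single-layer LSTM with tanh cell activation and a linear read-out to the
# three joint angles (degrees), trained with Adam on a weighted multi-joint
# MSE loss. The cell, backpropagation through time and Adam are implemented
# here in full.

#' LSTM hyperparameters
#'
#' Defaults follow the reference configuration: one layer, batch size 256,
#' hidden size 50, Adam at learning rate 0.001, input sequence length 5,
#' 500 epochs, tanh cell activation, and per-joint loss weights
#' (hip, knee, ankle) = (3, 1, 4).
#'
#' @param n_layers Number of LSTM layers (only 1 is supported).
#' @param batch_size Mini-batch size.
#' @param hidden_size Hidden-state width.
#' @param learning_rate Adam learning rate.
#' @param seq_len Input window length (samples).
#' @param epochs Training epochs.
#' @param loss_weights Length-3 weights (hip, knee, ankle) of the joint
#'   MSE terms.
#' @param seed Run seed controlling initialisation and shuffling.
#' @return List of class `lstm_hyperparams`.
#' @export
lstm_hyperparams <- function(n_layers = 1L, batch_size = 256L,
                             hidden_size = 50L, learning_rate = 0.001,
                             seq_len = 5L, epochs = 500L,
                             loss_weights = c(hip = 3, knee = 1, ankle = 4),
                             seed = 1L) {
  stopifnot(n_layers == 1L, batch_size >= 1, hidden_size >= 1,
            learning_rate > 0, seq_len >= 1, epochs >= 1,
            length(loss_weights) == 3, all(loss_weights >= 0))
  structure(list(n_layers = 1L, batch_size = as.integer(batch_size),
                 hidden_size = as.integer(hidden_size),
                 optimizer = "adam", learning_rate = learning_rate,
                 seq_len = as.integer(seq_len), epochs = as.integer(epochs),
                 activation = "tanh",
                 loss_weights = stats::setNames(as.numeric(loss_weights),
                                                joint_names()),
                 seed = as.integer(seed)),
            class = "lstm_hyperparams")
}

#' Build sliding windows over one gait cycle
#'
#' Emits one window per sample: window t holds samples
#' (t - seq_len + 1) .. t, left-padded by replicating the first sample so
#' every label sample gets a full-length window and hence a prediction
#' (the per-cycle NRMSE denominator needs predictions at every sample).
#' Windows never cross cycle boundaries. With `drop_partial = TRUE` the
#' first seq_len - 1 samples are dropped instead of padded.
#'
#' @param cycle A `gait_cycle` (see [build_cycles()]); its `features`
#'   matrix should already be normalised for training use.
#' @param seq_len Window length (default 5).
#' @param drop_partial Drop instead of pad the leading partial windows.
#' @return A `window_batch`: list with `x` (n x seq_len x n_features
#'   array), `y` (n x 3 label matrix, degrees), `keys` (data frame
#'   subject_id, cycle_id, sample_idx), `features` (channel names).
#' @export
build_windows <- function(cycle, seq_len = 5, drop_partial = FALSE) {
  if (seq_len < 1) stop("seq_len must be >= 1")
  f <- cycle$features
  n <- nrow(f)
  idx_last <- if (drop_partial) seq_len:n else seq_len(n)
  nw <- length(idx_last)
  x <- array(0, dim = c(nw, seq_len, ncol(f)),
             dimnames = list(NULL, NULL, colnames(f)))
  for (w in seq_len(nw)) {
    rows <- pmax(1L, (idx_last[w] - seq_len + 1L):idx_last[w])
    x[w, , ] <- f[rows, , drop = FALSE]
  }
  structure(list(
    x = x,
    y = cycle$labels[idx_last, , drop = FALSE],
    keys = data.frame(subject_id = cycle$subject_id,
                      cycle_id = cycle$cycle_id, sample_idx = idx_last),
    features = colnames(f)),
    class = "window_batch")
}

#' Concatenate window batches
#' @param batches List of `window_batch` objects with identical feature
#'   sets and window lengths.
#' @return One `window_batch`.
#' @export
combine_windows <- function(batches) {
  stopifnot(length(batches) >= 1)
  feats <- batches[[1]]$features
  seq_len_ <- dim(batches[[1]]$x)[2]
  for (b in batches) {
    stopifnot(identical(b$features, feats), dim(b$x)[2] == seq_len_)
  }
  nw <- sum(vapply(batches, function(b) dim(b$x)[1], integer(1)))
  x <- array(0, dim = c(nw, seq_len_, length(feats)),
             dimnames = list(NULL, NULL, feats))
  y <- matrix(0, nw, 3, dimnames = list(NULL, joint_names()))
  at <- 0L
  for (b in batches) {
    nb <- dim(b$x)[1]
    x[(at + 1):(at + nb), , ] <- b$x
    y[(at + 1):(at + nb), ] <- b$y
    at <- at + nb
  }
  structure(list(x = x, y = y,
                 keys = do.call(rbind, lapply(batches, `[[`, "keys")),
                 features = feats),
            class = "window_batch")
}

#' Weighted multi-joint MSE loss
#'
#' A * MSE(hip) + B * MSE(knee) + C * MSE(ankle) with (A, B, C) = (3, 1, 4)
#' by default.
#'
#' @param y Observed angles, n x 3 (hip, knee, ankle).
#' @param yhat Predicted angles, n x 3.
#' @param weights Length-3 joint weights.
#' @return Scalar loss.
#' @export
weighted_mse <- function(y, yhat, weights = c(3, 1, 4)) {
  if (!all(dim(y) == dim(yhat))) stop("y and yhat shapes differ")
  if (nrow(y) < 1) stop("need at least one sample")
  stopifnot(ncol(y) == 3, length(weights) == 3)
  sum(weights * colMeans((y - yhat)^2))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Parameter initialisation. Gate weights follow the standard
# uniform(-1/sqrt(H), 1/sqrt(H)) scheme. The read-out is scale-matched to
# the targets: bias = per-joint label mean, weights uniform scaled by the
# per-joint label SD / sqrt(H), so the network starts at the labels' scale
# and Adam's bounded per-step displacement is spent aligning shape rather
# than climbing tens of degrees. (train_lstm immediately replaces the
# read-out by its closed-form ridge solution; this init only sets the
# fallback scale.)
init_lstm_params <- function(n_features, hidden, y_center, y_scale) {
  k <- 1 / sqrt(hidden)
  ru <- function(nr, nc, s) matrix(stats::runif(nr * nc, -s, s), nr, nc)
  list(Wx = ru(n_features, 4 * hidden, k),
       Wh = ru(hidden, 4 * hidden, k),
       b = stats::runif(4 * hidden, -k, k),
       Wy = sweep(ru(hidden, 3, 1), 2, y_scale / sqrt(hidden), "*"),
       by = y_center)
}

# Forward pass over a batch. X: B x T x F. Returns yhat and, if asked, the
# per-step cache needed by backprop.
lstm_forward <- function(params, X, cache = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- nrow(params$Wh)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  steps <- if (cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], nrow = B)
    z <- xt %*% params$Wx + h %*% params$Wh
    z <- sweep(z, 2, params$b, "+")
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    if (cache) {
      steps[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                         c_prev = c_prev, tc = tc, h_prev = h)
    }
    h <- o * tc
  }
  yhat <- sweep(h %*% params$Wy, 2, params$by, "+")
  list(yhat = yhat, h = h, steps = steps)
}

# Backward pass: gradient of the loss wrt all parameters, given
# dL/dyhat (B x 3).
lstm_backward <- function(params, fwd, dY) {
  H <- nrow(params$Wh)
  Tn <- length(fwd$steps)
  grads <- list(Wx = 0 * params$Wx, Wh = 0 * params$Wh, b = 0 * params$b,
                Wy = crossprod(fwd$h, dY), by = colSums(dY))
  dh <- dY %*% t(params$Wy)
  dc <- matrix(0, nrow(dY), H)
  for (t in rev(seq_len(Tn))) {
    s <- fwd$steps[[t]]
    do <- dh * s$tc
    dct <- dc + dh * s$o * (1 - s$tc^2)
    df <- dct * s$c_prev
    di <- dct * s$g
    dg <- dct * s$i
    dz <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do * s$o * (1 - s$o))
    grads$Wx <- grads$Wx + crossprod(s$xt, dz)
    grads$Wh <- grads$Wh + crossprod(s$h_prev, dz)
    grads$b <- grads$b + colSums(dz)
    dh <- dz %*% t(params$Wh)
    dc <- dct * s$f
  }
  grads
}

#' Train the LSTM joint-angle regressor
#'
#' Mini-batch gradient descent with Adam on the weighted multi-joint MSE.
#' Windows are shuffled every epoch with the run seed; with single-threaded
#' BLAS the result is a deterministic function of (windows, hp).
#'
#' Because the loss is separable over joints, the optimal linear read-out
#' for a fixed LSTM trunk is a per-joint least-squares problem. Training
#' exploits that twice: the read-out is initialised by a ridge solve of
#' the targets on the initial hidden states (a reservoir-style warm start,
#' so gradient steps are spent shaping the trunk rather than scaling the
#' output layer), and after the final epoch the read-out is re-solved in
#' closed form on the training windows — exact coordinate minimisation of
#' the training loss in the read-out parameters. Set `ridge_readout =
#' FALSE` for plain end-to-end gradient training.
#'
#' @param windows A `window_batch` of training windows (features already
#'   normalised with training-fold statistics; labels in degrees).
#' @param hp An [lstm_hyperparams()] object.
#' @param verbose Print the loss every 50 epochs.
#' @param ridge_readout Warm-start and finalise the read-out in closed
#'   form (default TRUE).
#' @param ridge_lambda Ridge regularisation of the read-out solves.
#' @return An `lstm_model`: parameters, hyperparameters, feature names and
#'   the per-epoch training-loss history.
#' @export
train_lstm <- function(windows, hp = lstm_hyperparams(), verbose = FALSE,
                       ridge_readout = TRUE, ridge_lambda = 1e-3) {
  stopifnot(inherits(windows, "window_batch"),
            inherits(hp, "lstm_hyperparams"))
  n <- dim(windows$x)[1]
  stopifnot(n >= 1, dim(windows$x)[2] == hp$seq_len)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(hp$seed)

  y_center <- colMeans(windows$y)
  y_scale <- pmax(apply(windows$y, 2, stats::sd), 1e-3)
  params <- init_lstm_params(length(windows$features), hp$hidden_size,
                             y_center, y_scale)
  solve_readout <- function(params) {
    hT <- lstm_forward(params, windows$x)$h
    Hc <- cbind(hT, 1)
    W <- solve(crossprod(Hc) + ridge_lambda * diag(ncol(Hc)),
               crossprod(Hc, windows$y))
    params$Wy <- W[-nrow(W), , drop = FALSE]
    params$by <- W[nrow(W), ]
    params
  }
  if (ridge_readout) params <- solve_readout(params)
  adam_m <- lapply(params, function(p) 0 * p)
  adam_v <- lapply(params, function(p) 0 * p)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  w <- hp$loss_weights

  loss_history <- numeric(hp$epochs)
  for (epoch in seq_len(hp$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    n_batches <- 0L
    for (start in seq(1, n, by = hp$batch_size)) {
      idx <- perm[start:min(start + hp$batch_size - 1L, n)]
      xb <- windows$x[idx, , , drop = FALSE]
      yb <- windows$y[idx, , drop = FALSE]
      B <- length(idx)
      fwd <- lstm_forward(params, xb, cache = TRUE)
      resid <- fwd$yhat - yb
      loss <- sum(w * colMeans(resid^2))
      if (!is.finite(loss)) {
        stop(sprintf(
          "NaN/Inf loss at epoch %d (lr %g, batch of %d, |resid| max %g)",
          epoch, hp$learning_rate, B, max(abs(resid))))
      }
      dY <- sweep(resid, 2, 2 * w / B, "*")
      grads <- lstm_backward(params, fwd, dY)
      step <- step + 1L
      lr_t <- hp$learning_rate * sqrt(1 - beta2^step) / (1 - beta1^step)
      for (p in names(params)) {
        adam_m[[p]] <- beta1 * adam_m[[p]] + (1 - beta1) * grads[[p]]
        adam_v[[p]] <- beta2 * adam_v[[p]] + (1 - beta2) * grads[[p]]^2
        params[[p]] <- params[[p]] -
          lr_t * adam_m[[p]] / (sqrt(adam_v[[p]]) + eps)
      }
      ep_loss <- ep_loss + loss
      n_batches <- n_batches + 1L
    }
    loss_history[epoch] <- ep_loss / n_batches
    if (verbose && epoch %% 50 == 0) {
      message(sprintf("epoch %d loss %.4f", epoch, loss_history[epoch]))
    }
  }
  if (ridge_readout) params <- solve_readout(params)
  structure(list(params = params, hp = hp, features = windows$features,
                 n_features = length(windows$features),
                 loss_history = loss_history),
            class = "lstm_model")
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf(
    "<lstm_model> %d features -> hidden %d -> 3 joints; final loss %.4f\n",
    x$n_features, x$hp$hidden_size, utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Predict joint angles for a batch of windows
#'
#' A pure function of (model, inputs): one (hip, knee, ankle) prediction
#' per window, in degrees, in the order of the batch's provenance keys.
#'
#' @param model An [train_lstm()] model.
#' @param windows A `window_batch` whose features match the model's.
#' @param chunk Windows per forward pass (memory control).
#' @return n x 3 matrix of predicted angles with the batch's `keys`
#'   attached as attribute `keys`.
#' @export
predict_lstm <- function(model, windows, chunk = 8192L) {
  stopifnot(inherits(model, "lstm_model"),
            inherits(windows, "window_batch"))
  if (!identical(windows$features, model$features)) {
    stop(sprintf("feature mismatch: model uses [%s], windows have [%s]",
                 paste(model$features, collapse = ","),
                 paste(windows$features, collapse = ",")))
  }
  n <- dim(windows$x)[1]
  out <- matrix(0, n, 3, dimnames = list(NULL, joint_names()))
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx, ] <- lstm_forward(model$params,
                               windows$x[idx, , , drop = FALSE])$yhat
  }
  attr(out, "keys") <- windows$keys
  out
}

#' Save / load a trained model
#'
#' The checkpoint is self-describing (hyperparameters, feature list,
#' parameter arrays) and reloads bit-exactly.
#'
#' @param model An `lstm_model`.
#' @param path Checkpoint file path.
#' @return `load_lstm_model` returns the model.
#' @export
save_lstm_model <- function(model, path) {
  stopifnot(inherits(model, "lstm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_lstm_model
#' @export
load_lstm_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "lstm_model"))
  model
}
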