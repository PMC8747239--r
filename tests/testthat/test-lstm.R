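# Window construction, the weighted loss, and the LSTM regressor itself.

test_that("windows replicate the first sample and never cross cycles", {
  set.seed(1)
  cy <- toy_cycle(matrix(rnorm(24 * 9), 24, 9), matrix(rnorm(24 * 3), 24, 3))
  wb <- build_windows(cy, seq_len = 5)
  expect_equal(dim(wb$x), c(24, 5, 9))
  # window for sample 1 is five copies of feature row 1
  for (t in 1:5) {
    expect_equal(wb$x[1, t, ], cy$features[1, ], ignore_attr = TRUE)
  }
  # window t's last row equals feature row t for all t (index oracle)
  for (t in 1:24) {
    expect_equal(wb$x[t, 5, ], cy$features[t, ], ignore_attr = TRUE)
    rows <- pmax(1, (t - 4):t)
    expect_equal(wb$x[t, , ], cy$features[rows, ], ignore_attr = TRUE)
  }
  expect_equal(wb$y, cy$labels[1:24, ])
  expect_error(build_windows(cy, seq_len = 0), "seq_len")
})

test_that("seq_len 1 degenerates to per-sample regression windows", {
  set.seed(2)
  cy <- toy_cycle(matrix(rnorm(10 * 4), 10, 4), matrix(rnorm(30), 10, 3))
  wb <- build_windows(cy, seq_len = 1)
  expect_equal(dim(wb$x), c(10, 1, 4))
  expect_equal(wb$x[, 1, ], cy$features, ignore_attr = TRUE)
})

test_that("drop_partial drops the first seq_len - 1 windows", {
  set.seed(3)
  cy <- toy_cycle(matrix(rnorm(12 * 3), 12, 3), matrix(rnorm(36), 12, 3))
  wb <- build_windows(cy, seq_len = 5, drop_partial = TRUE)
  expect_equal(dim(wb$x)[1], 8)
  expect_equal(wb$keys$sample_idx, 5:12)
})

test_that("weighted MSE follows the three-term formula", {
  set.seed(4)
  y <- matrix(rnorm(300), 100, 3)
  expect_equal(weighted_mse(y, y), 0)
  # equal per-joint MSE m with weights 3/1/4 gives 8m
  yhat <- y + 1
  expect_equal(weighted_mse(y, yhat), 8)

  yhat2 <- y + matrix(rnorm(300), 100, 3)
  oracle <- 0
  for (j in 1:3) {
    oracle <- oracle + c(3, 1, 4)[j] * mean((y[, j] - yhat2[, j])^2)
  }
  expect_equal(weighted_mse(y, yhat2), oracle, tolerance = 1e-10)
  expect_error(weighted_mse(y, yhat2[1:50, ]), "shapes")
})

test_that("weight vectors isolate single joints exactly", {
  set.seed(5)
  y <- matrix(rnorm(60), 20, 3)
  yhat <- y + matrix(rnorm(60), 20, 3)
  expect_equal(weighted_mse(y, yhat, c(1, 0, 0)), mean((y[, 1] - yhat[, 1])^2),
               tolerance = 1e-12)
  expect_equal(weighted_mse(y, yhat, c(0, 1, 0)), mean((y[, 2] - yhat[, 2])^2),
               tolerance = 1e-12)
  expect_equal(weighted_mse(y, yhat, c(0, 0, 1)), mean((y[, 3] - yhat[, 3])^2),
               tolerance = 1e-12)
})

test_that("backpropagation matches numerical gradients", {
  set.seed(6)
  Fn <- 4; H <- 6; B <- 5; Tn <- 5
  params <- init_lstm_params(Fn, H, y_center = c(1, 2, 3),
                             y_scale = c(1, 1, 1))
  X <- array(rnorm(B * Tn * Fn), c(B, Tn, Fn))
  Y <- matrix(rnorm(B * 3), B, 3)
  w <- c(3, 1, 4)
  lossfn <- function(pp) {
    yhat <- lstm_forward(pp, X)$yhat
    sum(w * colMeans((yhat - Y)^2))
  }
  fwd <- lstm_forward(params, X, cache = TRUE)
  dY <- sweep(fwd$yhat - Y, 2, 2 * w / B, "*")
  gr <- lstm_backward(params, fwd, dY)
  eps <- 1e-6
  for (p in names(params)) {
    idx <- sample(length(params[[p]]), min(5, length(params[[p]])))
    for (i in idx) {
      up <- params; up[[p]][i] <- up[[p]][i] + eps
      dn <- params; dn[[p]][i] <- dn[[p]][i] - eps
      g_num <- (lossfn(up) - lossfn(dn)) / (2 * eps)
      expect_equal(gr[[p]][i], g_num, tolerance = 1e-4)
    }
  }
})

test_that("a constant-label dataset is learned essentially exactly", {
  set.seed(7)
  cy <- toy_cycle(matrix(runif(40 * 9), 40, 9),
                  matrix(rep(c(10, 20, 30), each = 40), 40, 3))
  wb <- build_windows(cy)
  hp <- lstm_hyperparams(epochs = 50, seed = 1)
  model <- train_lstm(wb, hp)
  pred <- predict_lstm(model, wb)
  expect_lt(weighted_mse(wb$y, pred), 1e-3)
  expect_equal(colMeans(pred), c(hip = 10, knee = 20, ankle = 30),
               tolerance = 1e-2)
})

test_that("training is deterministic given the seed", {
  set.seed(8)
  wb <- combine_windows(lapply(random_cycles(3, seed = 8), build_windows))
  hp <- lstm_hyperparams(epochs = 5, hidden_size = 8, seed = 42)
  m1 <- train_lstm(wb, hp)
  m2 <- train_lstm(wb, hp)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss_history, m2$loss_history)
})

test_that("training loss decreases overall on a learnable problem", {
  trl <- quiet_trial(n_cycles = 8)
  cycles <- build_cycles(trl)
  st <- suppressWarnings(fit_minmax(cycles))
  cycles <- lapply(cycles, function(cy) {
    cy$features <- apply_minmax(cy$features, st)
    cy
  })
  wb <- combine_windows(lapply(cycles, build_windows))
  hp <- lstm_hyperparams(epochs = 60, seed = 3)
  model <- train_lstm(wb, hp, ridge_readout = FALSE)
  lh <- model$loss_history
  sm <- stats::filter(lh, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_gte(mean(diff(sm) <= 1e-8), 0.9)
  expect_lt(utils::tail(lh, 1), lh[1])
})

test_that("a bias-only model predicts its bias everywhere", {
  params <- init_lstm_params(9, 5, y_center = c(10, 20, 30),
                             y_scale = c(0, 0, 0))
  params$Wx[] <- 0; params$Wh[] <- 0; params$b[] <- 0; params$Wy[] <- 0
  model <- structure(list(params = params, hp = lstm_hyperparams(),
                          features = imu_channels(), n_features = 9,
                          loss_history = 0), class = "lstm_model")
  wb <- combine_windows(lapply(random_cycles(2, seed = 9), build_windows))
  pred <- predict_lstm(model, wb)
  expect_true(all(abs(sweep(pred, 2, c(10, 20, 30))) < 1e-12))
})

test_that("prediction is stateless across windows and batch splits", {
  set.seed(10)
  cycles <- random_cycles(4, seed = 10)
  wb <- combine_windows(lapply(cycles, build_windows))
  hp <- lstm_hyperparams(epochs = 2, hidden_size = 8, seed = 2)
  model <- train_lstm(wb, hp)
  full <- predict_lstm(model, wb)
  # halves concatenated equal the full batch
  n <- dim(wb$x)[1]
  half <- function(idx) {
    structure(list(x = wb$x[idx, , , drop = FALSE],
                   y = wb$y[idx, , drop = FALSE],
                   keys = wb$keys[idx, ], features = wb$features),
              class = "window_batch")
  }
  h1 <- predict_lstm(model, half(1:(n / 2)))
  h2 <- predict_lstm(model, half((n / 2 + 1):n))
  expect_equal(rbind(h1, h2), full, ignore_attr = TRUE)
  # permuting windows permutes predictions identically
  perm <- sample(n)
  pp <- predict_lstm(model, half(perm))
  expect_equal(pp, full[perm, ], ignore_attr = TRUE)
})

test_that("feature mismatch is rejected at prediction time", {
  wb <- combine_windows(lapply(random_cycles(1, seed = 11), build_windows))
  hp <- lstm_hyperparams(epochs = 1, hidden_size = 4, seed = 1)
  model <- train_lstm(wb, hp)
  bad <- wb
  bad$features <- bad$features[1:5]
  bad$x <- bad$x[, , 1:5, drop = FALSE]
  expect_error(predict_lstm(model, bad), "feature mismatch")
})

test_that("models round-trip through checkpoints bit-exactly", {
  wb <- combine_windows(lapply(random_cycles(1, seed = 12), build_windows))
  model <- train_lstm(wb, lstm_hyperparams(epochs = 1, hidden_size = 4,
                                           seed = 5))
  path <- tempfile(fileext = ".ckpt")
  save_lstm_model(model, path)
  expect_identical(load_lstm_model(path), model)
  unlink(path)
})
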