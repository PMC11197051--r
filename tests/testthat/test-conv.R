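tiny_linear_data <- function(Tn = 3000, C = 6, seed = 1, n_out = 3) {
  set.seed(seed)
  Fm <- matrix(abs(rnorm(Tn * C)), Tn, C)
  B <- matrix(rnorm(C * n_out, 0, 0.3), C, n_out)
  Y <- Fm %*% B
  trial <- rep(seq_len(Tn %/% 50), each = 50)[seq_len(Tn)]
  list(features = Fm, labels = Y, trial = trial)
}

tiny_spec <- function(...) {
  conv_spec_small(conv_filters = c(6, 6), dense = c(12, 12),
                  history = 6, learning_rate = 5e-3, batch_size = 128,
                  val_trials = 4, ...)
}

test_that("a realizable linear target is learned to near-zero validation error", {
  d <- tiny_linear_data()
  m <- fit_conv_regressor(d, tiny_spec(learning_rate = 1e-2,
                                       max_epochs = 100, patience = 20))
  # >90% of the label power explained, several times below the
  # mean-predictor baseline
  expect_lt(m$val_loss, 0.1 * mean(d$labels^2))
  base <- mean(sweep(d$labels, 2, colMeans(d$labels))^2)
  expect_lt(m$val_loss, base / 5)
})

test_that("permuting labels across trials collapses to the mean baseline", {
  d <- tiny_linear_data(Tn = 2000)
  set.seed(2)
  # permute labels at trial granularity: signal destroyed, marginals kept
  perm <- sample(unique(d$trial))
  idx <- unlist(lapply(perm, function(tr) which(d$trial == tr)))
  d_perm <- d
  d_perm$labels <- d$labels[idx, , drop = FALSE]
  m <- fit_conv_regressor(d_perm, tiny_spec(max_epochs = 25, patience = 8))
  base <- mean(sweep(d$labels, 2, colMeans(d$labels))^2)
  expect_gt(m$val_loss, 0.5 * base)
})

test_that("training is deterministic given the seed", {
  d <- tiny_linear_data(Tn = 1200)
  m1 <- fit_conv_regressor(d, tiny_spec(max_epochs = 5, seed = 7))
  m2 <- fit_conv_regressor(d, tiny_spec(max_epochs = 5, seed = 7))
  expect_identical(m1$curves, m2$curves)
  expect_identical(m1$layers, m2$layers)
  m3 <- fit_conv_regressor(d, tiny_spec(max_epochs = 5, seed = 8))
  expect_false(identical(m1$curves$train_loss, m3$curves$train_loss))
})

test_that("predictions are causal and batch equals streaming", {
  d <- tiny_linear_data(Tn = 600)
  m <- fit_conv_regressor(d, tiny_spec(max_epochs = 3))
  Fm <- d$features[1:200, ]
  p1 <- conv_predict(m, Fm)$values
  # altering the future must not change the present
  Fm2 <- Fm
  Fm2[150:200, ] <- 99
  p2 <- conv_predict(m, Fm2)$values
  expect_equal(p2[1:149, ], p1[1:149, ], tolerance = 1e-12)
  # batch prediction equals one-step-at-a-time prediction
  step <- t(vapply(1:50, function(t)
    conv_predict(m, Fm[1:t, , drop = FALSE])$values[t, ],
    numeric(ncol(p1))))
  expect_equal(step, p1[1:50, ], tolerance = 1e-10)
})

test_that("zero features give a constant output and histories reset per trial", {
  d <- tiny_linear_data(Tn = 600)
  m <- fit_conv_regressor(d, tiny_spec(max_epochs = 3))
  pz <- conv_predict(m, matrix(0, 40, ncol(d$features)))$values
  # constant once the zero-padded history has filled with the constant input
  h <- m$spec$history
  expect_equal(pz[h:40, ], matrix(pz[h, ], 41 - h, ncol(pz), byrow = TRUE),
               tolerance = 1e-12)
  # trial boundaries zero the history: sample 1 of a new trial matches a
  # fresh stream start
  Fm <- d$features[1:60, ]
  trial <- rep(1:2, each = 30)
  p_split <- conv_predict(m, Fm, trial)$values
  p_fresh <- conv_predict(m, Fm[31:60, , drop = FALSE])$values
  expect_equal(p_split[31:60, ], p_fresh, tolerance = 1e-12)
})

test_that("spec validation catches impossible architectures and budgets", {
  expect_error(conv_spec(history = 4, conv_filters = c(8, 8, 8, 8)),
               "history")
  expect_error(conv_spec(learning_rate = 0), "learning_rate")
  d <- tiny_linear_data(Tn = 300)
  expect_error(fit_conv_regressor(d, tiny_spec(val_trials = 10)),
               "validation")
})

test_that("the network beats the Kalman filter under envelope saturation", {
  # features saturate: the EMG-to-kinematics map is strongly non-linear, so
  # the linear-Gaussian observation model underfits while the network can
  # invert the saturation
  set.seed(10)
  Tn <- 4000
  C <- 6
  X <- matrix(0, Tn, 8)
  for (t in 2:Tn) X[t, ] <- 0.95 * X[t - 1, ] + rnorm(8, 0, 0.08)
  X <- pmin(pmax(X, -1), 1)
  B <- matrix(runif(8 * C, 0.3, 1), 8, C)
  drive <- tanh(4 * pmax(X, 0) %*% B) + 0.05 * matrix(rnorm(Tn * C), Tn, C)
  trial <- rep(seq_len(Tn %/% 100), each = 100)
  d <- list(features = drive, labels = X, trial = trial)
  test_idx <- trial > 30
  train <- list(features = drive[!test_idx, ], labels = X[!test_idx, ],
                trial = trial[!test_idx])
  kf <- fit_kalman(train, n_channels = C)
  kf_pred <- kalman_predict(kf, drive[test_idx, ])$values
  cnn <- fit_conv_regressor(train,
                            tiny_spec(max_epochs = 40, patience = 10))
  cnn_pred <- conv_predict(cnn, drive[test_idx, ],
                           trial[test_idx])$values
  rmse <- function(p) sqrt(mean((p - X[test_idx, ])^2))
  expect_lt(rmse(cnn_pred), rmse(kf_pred))
})
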