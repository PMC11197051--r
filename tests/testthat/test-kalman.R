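test_that("state model recovery: AR(1) labels give a ~0.9 diagonal A", {
  set.seed(1)
  Tn <- 5000
  X <- matrix(0, Tn, 8)
  for (t in 2:Tn) X[t, ] <- 0.9 * X[t - 1, ] + rnorm(8, 0, 0.05)
  Z <- X %*% matrix(rnorm(8 * 16, 0, 0.5), 8, 16) +
    matrix(rnorm(Tn * 16, 0, 0.01), Tn, 16)
  train <- list(features = Z, labels = X, trial = rep(1L, Tn))
  m <- fit_kalman(train, n_channels = 16)
  expect_equal(unname(diag(m$A)), rep(0.9, 8), tolerance = 0.02)
  expect_lt(max(abs(m$A - diag(diag(m$A)))), 0.05)
})

test_that("noise-free linear observations are recovered exactly at lambda 0", {
  set.seed(2)
  Tn <- 400
  X <- matrix(rnorm(Tn * 8), Tn, 8)
  H_true <- matrix(rnorm(8 * 12), 12, 8)
  Z <- X %*% t(H_true)
  train <- list(features = Z, labels = X, trial = rep(1L, Tn))
  m <- fit_kalman(train, ridge_lambda = 0, n_channels = 12)
  expect_equal(m$H, H_true, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(m$Q)), 1e-16)
})

test_that("duplicated feature columns fit without singularity when ridged", {
  set.seed(3)
  Tn <- 300
  X <- matrix(rnorm(Tn * 8), Tn, 8)
  z <- X[, 1] + rnorm(Tn, 0, 0.1)
  Z <- cbind(z, z, z, X[, 2])
  train <- list(features = Z, labels = X, trial = rep(1L, Tn))
  expect_no_error(fit_kalman(train, ridge_lambda = 1e-3, n_channels = 4))
  expect_error(fit_kalman(train, n_channels = 10), "channels")
})

test_that("recursive filter matches the batch conditioning oracle", {
  set.seed(4)
  for (case in 1:5) {
    k <- sample(2:4, 1)
    d <- sample(2:5, 1)
    Tn <- 40
    A <- random_stable(k)
    W <- random_spd(k, 0.05)
    H <- matrix(rnorm(d * k), d, k)
    Q <- random_spd(d, 0.1)
    sim <- simulate_lgss(A, W, H, Q, Tn)
    model <- structure(list(A = A, W = W, H = H, Q = Q,
                            channel_subset = seq_len(d), n_dof = k),
                       class = "kalman_model")
    got <- kalman_predict(model, sim$Y, clip = FALSE)$values
    want <- kalman_oracle(A, W, H, Q, sim$Y)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("exact-observation and static limits behave as expected", {
  set.seed(5)
  k <- 4
  Tn <- 60
  X <- matrix(rnorm(Tn * k), Tn, k)
  # H = identity, Q -> 0: predictions converge to the observations
  model <- structure(list(A = diag(k), W = diag(1, k), H = diag(k),
                          Q = diag(1e-12, k), channel_subset = 1:k,
                          n_dof = k), class = "kalman_model")
  out <- kalman_predict(model, X, clip = FALSE)$values
  expect_equal(out[-1, ], X[-1, ], tolerance = 1e-4)
  # W -> 0 with A = I: the state stays put at its converged value
  x0 <- rep(0.5, k)
  Yconst <- matrix(rep(x0, each = Tn), Tn, k)
  model2 <- structure(list(A = diag(k), W = diag(1e-14, k), H = diag(k),
                           Q = diag(0.1, k), channel_subset = 1:k,
                           n_dof = k), class = "kalman_model")
  out2 <- kalman_predict(model2, Yconst, clip = FALSE)$values
  expect_equal(out2[Tn, ], x0, tolerance = 1e-3)
  expect_lt(max(abs(diff(out2[(Tn - 10):Tn, ]))), 1e-3)
})

test_that("MKF threshold/rescale has its closed-form values", {
  x <- matrix(c(0.19, 0.6, -0.6, 1.0, -1.0, 0.2), 1)
  got <- mkf_postprocess(x, threshold = 0.20)
  expect_equal(as.numeric(got), c(0, 0.5, -0.5, 1, -1, 0), tolerance = 1e-12)
  expect_error(mkf_postprocess(x, threshold = 1), "threshold")
})

test_that("MKF is odd, monotone, continuous at the threshold, and fixes 0 and +/-1", {
  v <- seq(-1, 1, by = 0.001)
  y <- as.numeric(mkf_postprocess(matrix(v, ncol = 1)))
  yr <- as.numeric(mkf_postprocess(matrix(rev(-v), ncol = 1)))
  expect_equal(y, -rev(yr), tolerance = 1e-12)       # odd
  expect_true(all(diff(y) >= -1e-12))                # monotone nondecreasing
  eps <- 1e-6
  below <- as.numeric(mkf_postprocess(matrix(0.2 - eps, 1)))
  above <- as.numeric(mkf_postprocess(matrix(0.2 + eps, 1)))
  expect_lt(abs(above - below), 1e-5)                # continuous at threshold
  expect_equal(as.numeric(mkf_postprocess(matrix(c(0, 1, -1), 1))),
               c(0, 1, -1))                          # fixed points
})

test_that("the temporal prior helps when the state-space model holds", {
  # on data generated exactly from (A, W, H, Q) the filter is the optimal
  # sequential estimator, so it must beat the per-sample likelihood-only
  # (GLS) inversion that ignores the prior
  set.seed(6)
  wins <- 0
  for (case in 1:5) {
    k <- 4; d <- 6; Tn <- 300
    A <- random_stable(k, 0.9)
    W <- random_spd(k, 0.02)
    H <- matrix(rnorm(d * k), d, k)
    Q <- random_spd(d, 0.5)
    sim <- simulate_lgss(A, W, H, Q, Tn, prior_var = 1)
    model <- structure(list(A = A, W = W, H = H, Q = Q,
                            channel_subset = seq_len(d), n_dof = k),
                       class = "kalman_model")
    kf <- kalman_predict(model, sim$Y, prior_var = 1, clip = FALSE)$values
    Qi <- solve(Q)
    G <- solve(t(H) %*% Qi %*% H + diag(1e-9, k), t(H) %*% Qi)
    gls <- sim$Y %*% t(G)
    rmse <- function(p) sqrt(mean((p - sim$X)^2))
    wins <- wins + (rmse(kf) < rmse(gls))
  }
  expect_equal(wins, 5)
})

test_that("on simulated sessions both decoders beat the label-mean baseline", {
  d <- ml_datasets_fixture()
  ds <- d$mirror
  folds <- make_folds(ds, 8, k = 1, seed = 2)
  tr <- myolabel:::subset_dataset(ds, folds[[1]]$train)
  te <- myolabel:::subset_dataset(ds, folds[[1]]$test)
  m <- fit_kalman(tr, n_channels = 24)
  rmse <- function(pred) sqrt(mean((pred - te$labels)^2))
  kf_pred <- matrix(0, nrow(te$features), 8)
  for (trial in unique(te$trial)) {
    idx <- te$trial == trial
    kf_pred[idx, ] <- kalman_predict(m, te$features[idx, , drop = FALSE])$values
  }
  # per-sample GLS using the likelihood model alone (no temporal prior)
  Zs <- sweep(te$features[, m$channel_subset], 2, m$obs_intercept)
  Qi <- solve(m$Q)
  G <- solve(t(m$H) %*% Qi %*% m$H + diag(1e-3, 8), t(m$H) %*% Qi)
  gls_pred <- pmin(pmax(Zs %*% t(G), -1), 1)
  mean_pred <- matrix(colMeans(tr$labels), nrow(te$labels), 8, byrow = TRUE)
  expect_lt(rmse(kf_pred), rmse(mean_pred))
  expect_lt(rmse(gls_pred), rmse(mean_pred))
})
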