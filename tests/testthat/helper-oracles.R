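# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own code paths.

# MAV by direct per-window mean of absolute values
mav_oracle <- function(x, rate, window_s = 0.3, out_rate = 30) {
  n <- length(x)
  w <- round(window_s * rate)
  n_out <- floor((n - 1) / rate * out_rate) + 1
  sapply(seq_len(n_out), function(i) {
    k_end <- min(floor((i - 1) / out_rate * rate) + 1, n)
    k_start <- max(1, k_end - w + 1)
    mean(abs(x[k_start:k_end]))
  })
}

# Kalman filter state estimates by conditioning the joint Gaussian of
# (x_t, y_{1:t}) -- no recursion, pure covariance algebra.
kalman_oracle <- function(A, W, H, Q, Y, prior_var = 10) {
  k <- nrow(A)
  d <- nrow(H)
  Tn <- nrow(Y)
  # state covariances: x_1 ~ N(0, P0), x_t = A x_{t-1} + w_t
  P <- vector("list", Tn)
  P[[1]] <- diag(prior_var, k)
  for (t in 2:Tn) P[[t]] <- A %*% P[[t - 1]] %*% t(A) + W
  # Cov(x_t, x_s) for t >= s is A^(t-s) P_s
  Apow <- vector("list", Tn)
  Apow[[1]] <- diag(k)
  for (j in 2:Tn) Apow[[j]] <- A %*% Apow[[j - 1]]
  xcov <- function(t, s) {   # Cov(x_t, x_s)
    if (t >= s) Apow[[t - s + 1]] %*% P[[s]] else t(xcov(s, t))
  }
  est <- matrix(0, Tn, k)
  for (t in seq_len(Tn)) {
    Syy <- matrix(0, d * t, d * t)
    Sxy <- matrix(0, k, d * t)
    for (s1 in seq_len(t)) {
      for (s2 in seq_len(t)) {
        blk <- H %*% xcov(s1, s2) %*% t(H)
        if (s1 == s2) blk <- blk + Q
        Syy[(s1 - 1) * d + 1:d, (s2 - 1) * d + 1:d] <- blk
      }
      Sxy[, (s1 - 1) * d + 1:d] <- xcov(t, s1) %*% t(H)
    }
    yv <- as.vector(t(Y[seq_len(t), , drop = FALSE]))
    est[t, ] <- Sxy %*% solve(Syy, yv)
  }
  est
}

random_spd <- function(d, scale = 1) {
  m <- matrix(rnorm(d * d), d, d)
  crossprod(m) / d * scale + diag(1e-3, d)
}

random_stable <- function(k, radius = 0.7) {
  m <- matrix(rnorm(k * k), k, k)
  m / max(Mod(eigen(m, only.values = TRUE)$values)) * radius
}

# simulate from a linear-Gaussian state-space model (x_1 ~ N(0, P0))
simulate_lgss <- function(A, W, H, Q, Tn, prior_var = 10) {
  k <- nrow(A)
  d <- nrow(H)
  cW <- chol(W)
  cQ <- chol(Q)
  X <- matrix(0, Tn, k)
  X[1, ] <- rnorm(k, 0, sqrt(prior_var))
  for (t in 2:Tn) X[t, ] <- A %*% X[t - 1, ] + t(cW) %*% rnorm(k)
  Y <- X %*% t(H) + matrix(rnorm(Tn * d), Tn, d) %*% cQ
  list(X = X, Y = Y)
}
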