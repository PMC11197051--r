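#' Fit a linear Kalman decoder
#'
#' The state is the 8-DOF normalized kinematic position. The prior model
#' (`A`, `W`) is least-squares regression of `x_t` on `x_{t-1}` over
#' consecutive within-trial sample pairs, with `W` the residual covariance.
#' The likelihood model regresses the selected feature channels on the
#' kinematics by ridge regression: `H` maps state to observations and `Q` is
#' the observation residual covariance, diagonal-loaded by `ridge_lambda`.
#' Channels are selected as the `n_channels` feature columns with the
#' highest absolute correlation to any DOF.
#'
#' @param train A [build_training_dataset()] result (or any list with
#'   `features`, `labels` matrices and a per-sample `trial` vector).
#' @param ridge_lambda Ridge/diagonal loading (default 1e-3). With 0 and
#'   collinear features the normal equations are singular and an error
#'   suggests a positive value.
#' @param n_channels Number of feature channels kept (default 48).
#' @return A `kalman_model` with `A`, `W`, `H`, `Q`, `channel_subset`,
#'   `ridge_lambda`.
#' @export
fit_kalman <- function(train, ridge_lambda = 1e-3, n_channels = 48) {
  X <- as.matrix(train$labels)
  Z <- as.matrix(train$features)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples")
  if (nrow(Z) != n) stop("labels and features must be aligned")
  if (n_channels > ncol(Z)) stop("n_channels exceeds available feature columns")
  trial <- train$trial %||% rep(1L, n)

  same <- trial[-1] == trial[-n]
  X1 <- X[-n, , drop = FALSE][same, , drop = FALSE]
  X2 <- X[-1, , drop = FALSE][same, , drop = FALSE]
  # ridge-load the state model as well: a DOF that never moves in the
  # training labels (e.g. an untargeted digit) has zero variance and makes
  # the plain normal equations exactly singular
  G <- crossprod(X1) + diag(ridge_lambda, ncol(X1))
  if (rcond_sym(G) < 1e-12)
    stop("singular normal equations for the state model; use ridge_lambda > 0")
  At <- solve(G, crossprod(X1, X2))
  A <- t(At)
  W <- crossprod(X2 - X1 %*% At) / nrow(X1)

  cors <- suppressWarnings(abs(stats::cor(Z, X)))
  cors[!is.finite(cors)] <- 0
  score <- apply(cors, 1, max)
  sel <- order(score, decreasing = TRUE)[seq_len(n_channels)]
  sel <- sort(sel)
  Zs <- Z[, sel, drop = FALSE]

  # observation model with an intercept (the EMG envelope has a resting
  # baseline): z ~ H x + c, fitted on centered variables
  xbar <- colMeans(X)
  zbar <- colMeans(Zs)
  Xc <- sweep(X, 2, xbar)
  Zc <- sweep(Zs, 2, zbar)
  GX <- crossprod(Xc) + diag(ridge_lambda, ncol(X))
  if (rcond_sym(GX) < 1e-12)
    stop("singular normal equations for the observation model; ",
         "use ridge_lambda > 0")
  B <- solve(GX, crossprod(Xc, Zc))
  H <- t(B)
  obs_intercept <- zbar - as.numeric(H %*% xbar)
  R <- Zc - Xc %*% B
  Q <- crossprod(R) / n + diag(ridge_lambda, ncol(Zs))

  structure(list(A = A, W = W, H = H, Q = Q,
                 obs_intercept = obs_intercept,
                 channel_subset = sel,
                 channel_names = colnames(Z)[sel],
                 ridge_lambda = ridge_lambda,
                 n_dof = ncol(X)),
            class = "kalman_model")
}

rcond_sym <- function(m) {
  ev <- tryCatch(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(0, 1))
  if (max(abs(ev)) == 0) 0 else min(abs(ev)) / max(abs(ev))
}

#' @export
print.kalman_model <- function(x, ...) {
  cat(sprintf("<kalman_model> %d DOFs, %d feature channels, lambda=%g\n",
              x$n_dof, length(x$channel_subset), x$ridge_lambda))
  invisible(x)
}

#' Run the Kalman filter over a feature stream
#'
#' Standard predict/update recursion. The state starts at 0 with a large
#' prior covariance; the output is clipped to [-1, 1] unless `clip = FALSE`.
#'
#' @param model A [fit_kalman()] result.
#' @param features A [feature_matrix()], a numeric matrix containing the
#'   model's channel subset (by column count of the training features), or a
#'   matrix already restricted to the subset (d columns).
#' @param prior_var Initial state variance (default 10).
#' @param clip Clip the output to the normalized range (default TRUE).
#' @return A [kinematic_trace()] of decoded kinematics.
#' @export
kalman_predict <- function(model, features, prior_var = 10, clip = TRUE) {
  Z <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  rate <- if (inherits(features, "feature_matrix")) features$rate else 30
  d <- length(model$channel_subset)
  if (ncol(Z) != d) {
    if (max(model$channel_subset) > ncol(Z))
      stop("features lack the model's channel subset")
    Z <- Z[, model$channel_subset, drop = FALSE]
  }
  A <- model$A; W <- model$W; H <- model$H; Q <- model$Q
  icpt <- model$obs_intercept %||% rep(0, nrow(H))
  k <- model$n_dof
  x <- rep(0, k)
  P <- diag(prior_var, k)
  Tn <- nrow(Z)
  out <- matrix(0, Tn, k)
  I_k <- diag(k)
  for (t in seq_len(Tn)) {
    if (t > 1L) {
      x <- A %*% x
      P <- A %*% P %*% t(A) + W
    }
    S <- H %*% P %*% t(H) + Q
    Sc <- tryCatch(chol(S), error = function(e)
      stop("innovation covariance is not positive definite ",
           "(ill-conditioned Q)"))
    K <- P %*% t(H) %*% chol2inv(Sc)
    x <- x + K %*% (Z[t, ] - icpt - H %*% x)
    P <- (I_k - K %*% H) %*% P
    P <- (P + t(P)) / 2
    out[t, ] <- x
  }
  if (clip) out <- pmin(pmax(out, -1), 1)
  colnames(out) <- if (k == N_DOF) dof_names() else NULL
  kinematic_trace(out, rate, NULL)
}

#' Modified-Kalman threshold/rescale post-processing
#'
#' Per sample and DOF with magnitude m = |value|: below the threshold the
#' output is 0; above it, the magnitude is rescaled linearly so the
#' threshold maps to 0 and the full range maps to 1, the sign is restored,
#' an optional gain applied, and the result clipped to [-1, 1].
#'
#' @param pred A [kinematic_trace()] or numeric matrix in [-1, 1].
#' @param threshold Fraction of the full range zeroed out (default 0.20).
#' @param gain Output multiplier (default 1, i.e. unused).
#' @return Same type as `pred`.
#' @export
mkf_postprocess <- function(pred, threshold = 0.20, gain = 1.0) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  v <- if (inherits(pred, "kinematic_trace")) pred$values else pred
  m <- abs(v)
  out <- sign(v) * pmax(m - threshold, 0) / (1 - threshold) * gain
  out <- pmin(pmax(out, -1), 1)
  if (inherits(pred, "kinematic_trace"))
    kinematic_trace(out, pred$rate, pred$boundaries)
  else out
}
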