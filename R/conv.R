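#' Convolutional regressor hyperparameters
#'
#' The regressor maps a spatiotemporal "image" of the last `history`
#' feature samples (time x channels) to the 8-DOF kinematic position. The
#' default architecture has eight weighted layers: four temporal
#' convolutions (kernel `kernel` along the time axis, shared across
#' positions), a mean-pooling stage over the remaining time positions,
#' three dense hidden layers, and the linear output layer. Trained by Adam
#' with early stopping on a held-out-trial validation loss.
#'
#' @param history Number of feature samples in the image (default 10).
#' @param conv_filters Filter counts of the convolution layers.
#' @param kernel Temporal kernel width (default 3).
#' @param dense Hidden sizes of the dense layers.
#' @param learning_rate Adam step size (offline default 1e-4).
#' @param batch_size Minibatch size.
#' @param max_epochs,patience Epoch budget and early-stopping patience.
#' @param val_trials Number of training trials reserved for validation.
#' @param seed Seed for initialization and batch shuffling.
#' @return A `conv_spec` list.
#' @export
conv_spec <- function(history = 10, conv_filters = c(16, 16, 16, 16),
                      kernel = 3, dense = c(32, 32, 32),
                      learning_rate = 1e-4, batch_size = 1024,
                      max_epochs = 200, patience = 20, val_trials = 5,
                      seed = 1L) {
  if (history < 1) stop("history must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  pos <- history
  for (f in conv_filters) {
    pos <- pos - (kernel - 1)
    if (pos < 1) stop("convolution stack consumes more time positions than ",
                      "the history provides")
  }
  structure(list(history = as.integer(history),
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), dense = as.integer(dense),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_trials = as.integer(val_trials),
                 seed = as.integer(seed)),
            class = "conv_spec")
}

#' Reduced desk-scale convolutional spec
#'
#' Halved layer widths and a short epoch budget with a faster step size, so
#' a full dataset-size sweep trains in minutes on one CPU.
#'
#' @param ... Overrides passed to [conv_spec()].
#' @return A `conv_spec`.
#' @export
conv_spec_small <- function(...) {
  args <- list(conv_filters = c(8, 8, 8, 8), dense = c(16, 16, 16),
               learning_rate = 2e-3, batch_size = 256,
               max_epochs = 25, patience = 6)
  args[names(list(...))] <- list(...)
  do.call(conv_spec, args)
}

# Lagged design matrix: column block j (of `history`) holds the features at
# lag history - j (oldest first), zeroed where the lag crosses a trial start.
build_history_blocks <- function(features, history, trial = NULL) {
  Fm <- as.matrix(features)
  Tn <- nrow(Fm)
  C <- ncol(Fm)
  if (is.null(trial)) trial <- rep(1L, Tn)
  X <- matrix(0, Tn, history * C)
  for (j in seq_len(history)) {
    l <- history - j
    src <- seq_len(Tn) - l
    ok <- src >= 1L
    ok[ok] <- trial[src[ok]] == trial[which(ok)]
    cols <- (j - 1L) * C + seq_len(C)
    X[ok, cols] <- Fm[src[ok], , drop = FALSE]
  }
  X
}

conv_net_init <- function(spec, n_channels, n_out) {
  widths_in <- c(n_channels, spec$conv_filters)
  layers <- list()
  for (l in seq_along(spec$conv_filters)) {
    fin <- spec$kernel * widths_in[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fin * spec$conv_filters[l], 0,
                              sqrt(2 / fin)), fin, spec$conv_filters[l]),
      b = rep(0, spec$conv_filters[l]), type = "conv")
  }
  din <- spec$conv_filters[length(spec$conv_filters)]
  for (h in c(spec$dense, n_out)) {
    layers[[length(layers) + 1L]] <- list(
      W = matrix(stats::rnorm(din * h, 0, sqrt(2 / din)), din, h),
      b = rep(0, h),
      type = if (h == n_out && length(layers) + 1L ==
                 length(spec$conv_filters) + length(spec$dense) + 1L)
        "linear" else "dense")
    din <- h
  }
  layers
}

conv_net_forward <- function(layers, spec, X, keep = FALSE) {
  nconv <- length(spec$conv_filters)
  pos <- spec$history
  A <- X
  cache <- if (keep) list() else NULL
  for (l in seq_len(nconv)) {
    fin_w <- ncol(A) / pos
    pout <- pos - spec$kernel + 1L
    fo <- ncol(layers[[l]]$W)
    Z <- matrix(0, nrow(A), pout * fo)
    for (p in seq_len(pout)) {
      cols <- ((p - 1L) * fin_w + 1L):((p + spec$kernel - 1L) * fin_w)
      Z[, (p - 1L) * fo + seq_len(fo)] <-
        sweep(A[, cols, drop = FALSE] %*% layers[[l]]$W, 2,
              layers[[l]]$b, `+`)
    }
    Anew <- pmax(Z, 0)
    if (keep) cache[[paste0("L", l)]] <- list(A_in = A, Z = Z, pos_in = pos,
                                             pos_out = pout)
    A <- Anew
    pos <- pout
  }
  # mean pool over remaining time positions
  fo <- ncol(A) / pos
  P <- matrix(0, nrow(A), fo)
  for (p in seq_len(pos)) P <- P + A[, (p - 1L) * fo + seq_len(fo)]
  P <- P / pos
  if (keep) cache$pool <- list(pos = pos, fo = fo)
  A <- P
  for (l in (nconv + 1L):length(layers)) {
    Z <- sweep(A %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    last <- l == length(layers)
    Anew <- if (last) Z else pmax(Z, 0)
    if (keep) cache[[paste0("L", l)]] <- list(A_in = A, Z = Z)
    A <- Anew
  }
  if (keep) list(out = A, cache = cache) else A
}

conv_net_backward <- function(layers, spec, cache, dOut) {
  nconv <- length(spec$conv_filters)
  grads <- vector("list", length(layers))
  dA <- dOut
  for (l in rev((nconv + 1L):length(layers))) {
    cc <- cache[[paste0("L", l)]]
    dZ <- if (l == length(layers)) dA else dA * (cc$Z > 0)
    grads[[l]] <- list(W = crossprod(cc$A_in, dZ), b = colSums(dZ))
    dA <- dZ %*% t(layers[[l]]$W)
  }
  pool <- cache$pool
  dApos <- matrix(0, nrow(dA), pool$pos * pool$fo)
  for (p in seq_len(pool$pos))
    dApos[, (p - 1L) * pool$fo + seq_len(pool$fo)] <- dA / pool$pos
  dA <- dApos
  for (l in rev(seq_len(nconv))) {
    cc <- cache[[paste0("L", l)]]
    fo <- ncol(layers[[l]]$W)
    fin_w <- ncol(cc$A_in) / cc$pos_in
    gW <- matrix(0, nrow(layers[[l]]$W), fo)
    gb <- rep(0, fo)
    dAin <- matrix(0, nrow(dA), ncol(cc$A_in))
    for (p in seq_len(cc$pos_out)) {
      ocols <- (p - 1L) * fo + seq_len(fo)
      dZ <- dA[, ocols, drop = FALSE] * (cc$Z[, ocols, drop = FALSE] > 0)
      icols <- ((p - 1L) * fin_w + 1L):((p + spec$kernel - 1L) * fin_w)
      gW <- gW + crossprod(cc$A_in[, icols, drop = FALSE], dZ)
      gb <- gb + colSums(dZ)
      dAin[, icols] <- dAin[, icols] + dZ %*% t(layers[[l]]$W)
    }
    grads[[l]] <- list(W = gW, b = gb)
    dA <- dAin
  }
  grads
}

adam_init <- function(layers)
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))

adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in seq_along(layers)) {
    s <- state[[l]]
    g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layers[[l]]$W <- layers[[l]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

#' Fit the windowed convolutional regressor
#'
#' @param train A [build_training_dataset()] result (matrices `features`,
#'   `labels`, per-sample `trial` ids).
#' @param spec A [conv_spec()].
#' @param val_trials Optional explicit vector of trial ids to hold out for
#'   validation; by default `spec$val_trials` trials are sampled (seeded)
#'   from the training trials.
#' @return A `conv_regressor` with the trained layers, feature
#'   standardization, and the training/validation loss curves.
#' @export
fit_conv_regressor <- function(train, spec = conv_spec(), val_trials = NULL) {
  Fm <- as.matrix(train$features)
  Y <- as.matrix(train$labels)
  trial <- train$trial %||% rep(1L, nrow(Fm))
  set.seed(spec$seed)
  utr <- unique(trial)
  if (is.null(val_trials)) {
    if (spec$val_trials >= length(utr))
      stop("validation trials must be fewer than training trials")
    val_trials <- sample(utr, spec$val_trials)
  }
  is_val <- trial %in% val_trials

  mu <- colMeans(Fm)
  sdv <- apply(Fm, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Fs <- sweep(sweep(Fm, 2, mu), 2, sdv, `/`)
  X <- build_history_blocks(Fs, spec$history, trial)
  Xtr <- X[!is_val, , drop = FALSE]
  Ytr <- Y[!is_val, , drop = FALSE]
  Xva <- X[is_val, , drop = FALSE]
  Yva <- Y[is_val, , drop = FALSE]

  layers <- conv_net_init(spec, ncol(Fm), ncol(Y))
  state <- adam_init(layers)
  n <- nrow(Xtr)
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  curves <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
  step <- 0L
  wait <- 0L
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0
    nb <- 0L
    for (b0 in seq(1L, n, by = spec$batch_size)) {
      idx <- ord[b0:min(b0 + spec$batch_size - 1L, n)]
      fw <- conv_net_forward(layers, spec, Xtr[idx, , drop = FALSE],
                             keep = TRUE)
      err <- fw$out - Ytr[idx, , drop = FALSE]
      loss <- mean(err^2)
      if (!is.finite(loss)) stop("non-finite training loss")
      grads <- conv_net_backward(layers, spec, fw$cache,
                                 2 * err / length(err))
      step <- step + 1L
      upd <- adam_step(layers, grads, state, spec$learning_rate, step)
      layers <- upd$layers
      state <- upd$state
      tr_loss <- tr_loss + loss
      nb <- nb + 1L
    }
    val_pred <- conv_net_forward(layers, spec, Xva)
    val_loss <- mean((val_pred - Yva)^2)
    if (!is.finite(val_loss)) stop("non-finite validation loss")
    curves <- rbind(curves, data.frame(epoch = epoch,
                                       train_loss = tr_loss / nb,
                                       val_loss = val_loss))
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, layers = layers, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  structure(list(spec = spec, layers = best$layers,
                 feature_center = mu, feature_scale = sdv,
                 n_channels = ncol(Fm), n_out = ncol(Y),
                 val_trials = val_trials, val_loss = best$loss,
                 best_epoch = best$epoch, curves = curves),
            class = "conv_regressor")
}

#' @export
print.conv_regressor <- function(x, ...) {
  cat(sprintf(paste0("<conv_regressor> %d ch x %d history -> %d DOFs; ",
                     "best val MSE %.5f @ epoch %d/%d\n"),
              x$n_channels, x$spec$history, x$n_out, x$val_loss,
              x$best_epoch, nrow(x$curves)))
  invisible(x)
}

#' Predict kinematics with a fitted convolutional regressor
#'
#' Predictions are causal: the image at step t contains features up to t
#' only, zero-padded at the start of each trial (or stream), and the output
#' is clipped to [-1, 1].
#'
#' @param model A [fit_conv_regressor()] result.
#' @param features A [feature_matrix()] or numeric matrix with the model's
#'   channel count.
#' @param trial Optional per-sample trial ids; history does not cross trial
#'   boundaries.
#' @return A [kinematic_trace()].
#' @export
conv_predict <- function(model, features, trial = NULL) {
  Fm <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  rate <- if (inherits(features, "feature_matrix")) features$rate else 30
  if (ncol(Fm) != model$n_channels)
    stop("feature channel count does not match the trained model")
  Fs <- sweep(sweep(Fm, 2, model$feature_center), 2, model$feature_scale, `/`)
  X <- build_history_blocks(Fs, model$spec$history, trial)
  out <- conv_net_forward(model$layers, model$spec, X)
  out <- pmin(pmax(out, -1), 1)
  colnames(out) <- if (ncol(out) == N_DOF) dof_names() else NULL
  kinematic_trace(out, rate, NULL)
}
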