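#' Feature matrix container
#'
#' @param values Nonnegative numeric matrix, time x channels.
#' @param rate Feature sampling rate in Hz.
#' @param channel_names Column labels.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, rate, channel_names = colnames(values)) {
  values <- as.matrix(values)
  if (!is.null(channel_names)) colnames(values) <- channel_names
  structure(list(values = values, rate = rate), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d channels @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$rate))
  invisible(x)
}

#' Canonical feature channel names
#'
#' Single-ended channels first, then all unordered differential pairs
#' (i < j) in lexicographic order.
#'
#' @param n_channels Number of single-ended channels.
#' @param pairs Include differential pairs?
#' @return Character vector of channel names.
#' @export
mav_channel_names <- function(n_channels, pairs = TRUE) {
  nm <- sprintf("se%02d", seq_len(n_channels))
  if (pairs && n_channels >= 2) {
    ij <- pair_index(n_channels)
    nm <- c(nm, sprintf("df%02d_%02d", ij[, 1], ij[, 2]))
  }
  nm
}

pair_index <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  colnames(ij) <- c("i", "j")
  ij
}

#' Smoothed mean-absolute-value features with differential pairs
#'
#' For each output time on the `out_rate_hz` grid, the MAV of each
#' single-ended channel is the mean absolute value of the raw samples in the
#' trailing `window_s` window ending at that time (shorter at stream start:
#' the mean runs over the samples available so far). Differential-pair
#' features are the MAV of the raw difference `x_i - x_j`, computed at the
#' raw rate and windowed identically. Columns are ordered single-ended
#' first, then pairs (i < j) lexicographically.
#'
#' @param raw A [raw_emg()] object.
#' @param window_s Trailing window length, seconds (default 0.3).
#' @param out_rate_hz Output feature rate, Hz (default 30, the kinematic
#'   grid; each output sample uses raw samples up to its timestamp).
#' @param pairs Include differential pairs (default TRUE).
#' @param max_channels Optionally truncate the output to the first
#'   `max_channels` columns in canonical order (reduced desk-scale mode);
#'   only the needed pair columns are computed.
#' @return A [feature_matrix()].
#' @export
compute_mav_features <- function(raw, window_s = 0.3, out_rate_hz = 30,
                                 pairs = TRUE, max_channels = NULL) {
  x <- raw$values
  n <- nrow(x)
  nc <- ncol(x)
  w <- as.integer(round(window_s * raw$rate))
  if (w < 1) stop("window shorter than one raw sample")
  if (raw$rate < out_rate_hz)
    stop("raw rate below the output rate; resampling is not supported")
  n_out <- floor((n - 1) / raw$rate * out_rate_hz) + 1L
  # index of the last raw sample at-or-before each output timestamp
  k_end <- pmin(floor((seq_len(n_out) - 1) / out_rate_hz * raw$rate) + 1L, n)
  w_eff <- pmin(w, k_end)
  k_start <- k_end - w_eff  # cumsum index of sample before the window

  n_pairs <- if (pairs) nrow(pair_index(nc)) else 0L
  n_col_full <- nc + n_pairs
  n_col <- if (is.null(max_channels)) n_col_full else
    min(max_channels, n_col_full)
  out <- matrix(0, n_out, n_col)

  windowed <- function(absx) {
    cs <- c(0, cumsum(absx))
    (cs[k_end + 1L] - cs[k_start + 1L]) / w_eff
  }
  for (c in seq_len(min(nc, n_col)))
    out[, c] <- windowed(abs(x[, c]))
  if (n_col > nc) {
    ij <- pair_index(nc)
    for (p in seq_len(n_col - nc))
      out[, nc + p] <- windowed(abs(x[, ij[p, 1]] - x[, ij[p, 2]]))
  }
  nm <- mav_channel_names(nc, pairs = n_pairs > 0)[seq_len(n_col)]
  feature_matrix(out, out_rate_hz, nm)
}

#' Joint-angle normalization parameters
#'
#' @param rest_baseline Per-DOF resting angle.
#' @param flex_extreme,ext_extreme Per-DOF extreme angles; must satisfy
#'   `ext_extreme < rest_baseline < flex_extreme`.
#' @return A `normalization_params` object.
#' @export
normalization_params <- function(rest_baseline, flex_extreme, ext_extreme) {
  stopifnot(length(flex_extreme) == length(rest_baseline),
            length(ext_extreme) == length(rest_baseline))
  if (any(ext_extreme >= rest_baseline) || any(flex_extreme <= rest_baseline))
    stop("extremes must bracket the rest baseline (ext < rest < flex)")
  structure(list(rest_baseline = rest_baseline, flex_extreme = flex_extreme,
                 ext_extreme = ext_extreme), class = "normalization_params")
}

#' Estimate normalization parameters from a raw angle trace
#'
#' The rest baseline of each DOF is its average angle over the leading rest
#' window; extremes come from a calibration input when supplied, otherwise
#' from the per-session observed min/max of each DOF (post-hoc
#' normalization).
#'
#' @param raw_angles Numeric matrix, time x DOFs, raw angle units.
#' @param rate Sampling rate, Hz.
#' @param rest_window_s Length of the leading rest window, seconds.
#' @param extremes Optional list with `flex` and `ext` per-DOF vectors.
#' @return A [normalization_params()] object.
#' @export
estimate_normalization <- function(raw_angles, rate, rest_window_s = 15,
                                   extremes = NULL) {
  raw_angles <- as.matrix(raw_angles)
  n_rest <- as.integer(round(rest_window_s * rate))
  if (n_rest > nrow(raw_angles))
    stop("rest window longer than the trace")
  baseline <- colMeans(raw_angles[seq_len(n_rest), , drop = FALSE])
  if (is.null(extremes))
    extremes <- list(flex = apply(raw_angles, 2, max),
                     ext = apply(raw_angles, 2, min))
  normalization_params(baseline, extremes$flex, extremes$ext)
}

#' Normalize raw joint angles to [-1, 1]
#'
#' Angles at the rest baseline map to 0; angles map linearly to 1 at the
#' flexion/pronation extreme and to -1 at the extension/supination extreme,
#' clipped to [-1, 1].
#'
#' @param raw_angles Numeric matrix, time x DOFs.
#' @param params A [normalization_params()] object.
#' @param rate Sampling rate attached to the returned trace.
#' @param boundaries Optional trial boundaries for the returned trace.
#' @return A [kinematic_trace()].
#' @export
normalize_trace <- function(raw_angles, params, rate = 30, boundaries = NULL) {
  raw_angles <- as.matrix(raw_angles)
  b <- params$rest_baseline
  up <- params$flex_extreme - b
  dn <- b - params$ext_extreme
  if (any(up <= 0) || any(dn <= 0)) stop("degenerate normalization extremes")
  dev <- sweep(raw_angles, 2, b)
  pos <- sweep(pmax(dev, 0), 2, up, `/`)
  neg <- sweep(pmin(dev, 0), 2, dn, `/`)
  kinematic_trace(pmin(pmax(pos + neg, -1), 1), rate, boundaries)
}

#' Invert [normalize_trace()]
#'
#' @param trace A [kinematic_trace()] with values in [-1, 1].
#' @param params A [normalization_params()] object.
#' @return Numeric matrix of raw angles.
#' @export
denormalize_trace <- function(trace, params) {
  v <- trace$values
  b <- params$rest_baseline
  up <- params$flex_extreme - b
  dn <- b - params$ext_extreme
  pos <- sweep(pmax(v, 0), 2, up, `*`)
  neg <- sweep(pmin(v, 0), 2, dn, `*`)
  sweep(pos + neg, 2, b, `+`)
}

#' Align labels to EMG features by cross-correlation
#'
#' Correlates the summed absolute label trace (over DOFs) against the summed
#' mean-centered feature stream (over channels) at integer sample shifts in
#' `[-max_lag_s, +max_lag_s]`. The reported lag is the shift of the labels
#' relative to the features that maximizes the correlation: a positive lag
#' means the labels lag the features. The aligned labels are advanced by the
#' lag and both streams are trimmed to the overlapping support. Ties are
#' broken toward the smallest absolute lag, then toward the negative lag.
#'
#' @param labels A [kinematic_trace()].
#' @param features A [feature_matrix()] at the same rate and length.
#' @param max_lag_s Maximum absolute lag searched, seconds (default 0.5).
#' @return List with `labels` (shifted, trimmed trace), `features` (trimmed),
#'   `lag_s`, `lag_samples`, and the correlation profile `cor` (named by
#'   shift).
#' @export
align_labels_crosscorr <- function(labels, features, max_lag_s = 0.5) {
  a <- rowSums(abs(labels$values))
  b <- rowSums(sweep(features$values, 2, colMeans(features$values)))
  n <- length(a)
  if (length(b) != n) stop("labels and features must have equal lengths")
  if (labels$rate != features$rate)
    stop("labels and features must share a sampling rate")
  L <- as.integer(round(max_lag_s * labels$rate))
  if (L >= n / 2) stop("max_lag must be below half the stream length")
  shifts <- -L:L
  cors <- vapply(shifts, function(s) {
    t0 <- max(1L, 1L - s)
    t1 <- min(n, n - s)
    aa <- a[(t0:t1) + s]
    bb <- b[t0:t1]
    if (stats::sd(aa) == 0 || stats::sd(bb) == 0) 0 else stats::cor(aa, bb)
  }, numeric(1))
  best <- order(-cors, abs(shifts), shifts)[1L]
  lag <- shifts[best]
  t0 <- max(1L, 1L - lag)
  t1 <- min(n, n - lag)
  lab_out <- kinematic_trace(labels$values[(t0:t1) + lag, , drop = FALSE],
                             labels$rate, NULL)
  feat_out <- feature_matrix(features$values[t0:t1, , drop = FALSE],
                             features$rate)
  names(cors) <- shifts
  list(labels = lab_out, features = feat_out,
       lag_s = lag / labels$rate, lag_samples = lag, cor = cors)
}

#' Shift a trace in time, filling exposed edges with the rest value 0
#'
#' `shift_trace_zero(x, k)` advances the trace by `k` samples
#' (`out[t] = x[t + k]`), keeping length and trial boundaries intact --
#' the full-length counterpart of the trimming done by
#' [align_labels_crosscorr()].
#'
#' @param trace A [kinematic_trace()].
#' @param lag_samples Integer shift in samples.
#' @return A [kinematic_trace()] of identical length.
#' @export
shift_trace_zero <- function(trace, lag_samples) {
  v <- trace$values
  n <- nrow(v)
  out <- matrix(0, n, ncol(v), dimnames = dimnames(v))
  src <- seq_len(n) + lag_samples
  ok <- src >= 1L & src <= n
  out[ok, ] <- v[src[ok], , drop = FALSE]
  kinematic_trace(out, trace$rate, trace$boundaries)
}
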