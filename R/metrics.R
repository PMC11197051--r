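target_dofs_of <- function(schedule, i) {
  schedule$movements[[schedule$trials$movement_id[i]]]$target_dofs
}

#' Biomechanical coupling of the ground-truth hand
#'
#' For every trial, the mean absolute deviation from the current rest
#' reference over all movement-segment time points and all non-target DOFs
#' (mean across DOFs); the per-participant value is the median across
#' trials, in percent of the full normalized deviation. The rest reference
#' of a trial is the mean of the preceding rest interval (so a drifted
#' resting posture is not double-counted as coupling); the first trial is
#' referenced to the session-initial rest position (0).
#'
#' @param session A `session_data` object.
#' @return Coupling in percent.
#' @export
biomechanical_coupling <- function(session) {
  tr <- session$truth
  b <- tr$boundaries
  if (is.null(b)) stop("session lacks trial boundaries")
  sched <- session$schedule
  ref <- rep(0, N_DOF)
  per_trial <- numeric(nrow(b))
  for (i in seq_len(nrow(b))) {
    nt_dofs <- setdiff(seq_len(N_DOF), target_dofs_of(sched, i))
    mov <- tr$values[b[i, "onset"]:(b[i, "move_end"] - 1L), nt_dofs,
                     drop = FALSE]
    per_trial[i] <- mean(abs(sweep(mov, 2, ref[nt_dofs])))
    rest <- tr$values[b[i, "move_end"]:(b[i, "end"] - 1L), , drop = FALSE]
    ref <- colMeans(rest)
  }
  100 * stats::median(per_trial)
}

#' Resting-position drift of the ground-truth hand
#'
#' Mean absolute deviation from the session-initial rest position (0 in
#' normalized units) over each rest interval's time points, averaged across
#' all 8 DOFs; the per-participant value is the median across rest
#' intervals, in percent of the full normalized deviation.
#'
#' @param session A `session_data` object.
#' @return Drift in percent.
#' @export
rest_drift <- function(session) {
  tr <- session$truth
  b <- tr$boundaries
  if (is.null(b)) stop("session lacks trial boundaries")
  per_interval <- vapply(seq_len(nrow(b)), function(i) {
    rest <- tr$values[b[i, "move_end"]:(b[i, "end"] - 1L), , drop = FALSE]
    mean(abs(rest))
  }, numeric(1))
  if (length(per_interval) == 0) stop("schedule has no rest intervals")
  100 * stats::median(per_interval)
}

trial_peaks <- function(trace, schedule, boundaries) {
  nt <- nrow(boundaries)
  mag <- numeric(nt)
  tpk <- numeric(nt)
  for (i in seq_len(nt)) {
    dofs <- target_dofs_of(schedule, i)
    win <- boundaries[i, "start"]:(boundaries[i, "end"] - 1L)
    if (length(win) == 0) stop("trial window contains no samples")
    seg <- abs(trace$values[win, dofs, drop = FALSE])
    pk <- numeric(length(dofs))
    pt <- numeric(length(dofs))
    for (j in seq_along(dofs)) {
      k <- which.max(seg[, j])  # earliest sample on plateaus
      pk[j] <- seg[k, j]
      pt[j] <- (win[k] - 1) / trace$rate
    }
    mag[i] <- mean(pk)
    tpk[i] <- mean(pt)
  }
  list(magnitude = mag, time_s = tpk)
}

#' Spatial accuracy and precision of training labels
#'
#' Per trial, the peak magnitude is the maximum absolute target-DOF value
#' within the trial window (combination movements average the per-DOF
#' peaks); the magnitude error is `|peak(labels) - peak(truth)| * 100`.
#' Returns the mean (accuracy) and dispersion (precision, standard
#' deviation by default) across trials.
#'
#' @param labels,truth [kinematic_trace()]s on the same sample grid.
#' @param schedule The session's [build_schedule()] result.
#' @param boundaries Trial boundaries (defaults to those of `truth`).
#' @param dispersion `"sd"` (default, matching the reported units) or
#'   `"var"`.
#' @return List with `mean_pct`, `disp_pct`, and the per-trial `errors_pct`.
#' @export
magnitude_error_stats <- function(labels, truth, schedule,
                                  boundaries = truth$boundaries,
                                  dispersion = c("sd", "var")) {
  dispersion <- match.arg(dispersion)
  pl <- trial_peaks(labels, schedule, boundaries)
  pt <- trial_peaks(truth, schedule, boundaries)
  err <- 100 * abs(pl$magnitude - pt$magnitude)
  list(mean_pct = mean(err),
       disp_pct = if (dispersion == "sd") stats::sd(err) else stats::var(err),
       errors_pct = err)
}

#' Temporal accuracy and precision of training labels
#'
#' Per trial, the signed timing error is the time of the label peak minus
#' the time of the ground-truth peak (earliest sample on plateaus;
#' combination movements average the per-DOF peak times), in ms. Returns
#' the mean (signed), the mean of absolute errors, and the dispersion.
#'
#' @inheritParams magnitude_error_stats
#' @return List with `mean_ms` (signed), `abs_mean_ms`, `disp_ms`, and the
#'   per-trial `errors_ms`.
#' @export
timing_error_stats <- function(labels, truth, schedule,
                               boundaries = truth$boundaries,
                               dispersion = c("sd", "var")) {
  dispersion <- match.arg(dispersion)
  if (labels$rate != truth$rate) stop("traces must share a sampling rate")
  pl <- trial_peaks(labels, schedule, boundaries)
  pt <- trial_peaks(truth, schedule, boundaries)
  err <- 1000 * (pl$time_s - pt$time_s)
  list(mean_ms = mean(err), abs_mean_ms = mean(abs(err)),
       disp_ms = if (dispersion == "sd") stats::sd(err) else stats::var(err),
       errors_ms = err)
}

#' Pooled RMSE between two traces
#'
#' Root mean squared error over all DOFs and time points, normalized units.
#'
#' @param labels,truth [kinematic_trace()]s of identical shape.
#' @return RMSE (scalar).
#' @export
trace_rmse <- function(labels, truth) {
  if (!all(dim(labels$values) == dim(truth$values)))
    stop("traces must have identical shapes")
  sqrt(mean((labels$values - truth$values)^2))
}

#' Full label-quality report for one session and paradigm
#'
#' Mimic labels are the preprogrammed virtual trace, lag-corrected against
#' the EMG features by cross-correlation before any metric is computed (the
#' reaction-time delay is accounted for by temporal alignment, as a decoder
#' pipeline would); mirror labels are the contralateral-hand trace, used
#' as-is. Coupling and drift are properties of the ground-truth hand alone
#' and are identical across paradigms.
#'
#' @param session A `session_data` object.
#' @param paradigm `"mimic"` or `"mirror"`.
#' @param features Optional precomputed [feature_matrix()] for the
#'   alignment; when NULL and needed, single-ended MAV features are computed
#'   from the session EMG.
#' @param align Lag-correct mimic labels (default TRUE).
#' @param dispersion Passed to the error-stat operations.
#' @return A `label_quality` list with fields `paradigm`, `coupling_pct`,
#'   `drift_pct`, `mag_err_mean_pct`, `mag_err_disp_pct`, `timing_err_mean_ms`
#'   (signed), `timing_err_abs_mean_ms`, `timing_err_disp_ms`, `rmse`,
#'   `align_lag_s` and `n_trials`.
#' @export
label_quality_report <- function(session, paradigm = c("mimic", "mirror"),
                                 features = NULL, align = TRUE,
                                 dispersion = "sd") {
  paradigm <- match.arg(paradigm)
  truth <- session$truth
  lag_s <- NA_real_
  if (paradigm == "mimic") {
    labels <- session$virtual
    if (align) {
      if (is.null(features)) {
        if (is.null(session$emg))
          stop("mimic alignment needs EMG-derived features; simulate with EMG ",
               "or pass `features`")
        features <- compute_mav_features(session$emg, pairs = FALSE)
      }
      al <- align_labels_crosscorr(session$virtual, features)
      labels <- shift_trace_zero(session$virtual, al$lag_samples)
      lag_s <- al$lag_s
    }
  } else {
    labels <- session$mirror
  }
  mag <- magnitude_error_stats(labels, truth, session$schedule,
                               dispersion = dispersion)
  tim <- timing_error_stats(labels, truth, session$schedule,
                            dispersion = dispersion)
  structure(list(
    paradigm = paradigm,
    coupling_pct = biomechanical_coupling(session),
    drift_pct = rest_drift(session),
    mag_err_mean_pct = mag$mean_pct,
    mag_err_disp_pct = mag$disp_pct,
    timing_err_mean_ms = tim$mean_ms,
    timing_err_abs_mean_ms = tim$abs_mean_ms,
    timing_err_disp_ms = tim$disp_ms,
    rmse = trace_rmse(labels, truth),
    align_lag_s = lag_s,
    n_trials = n_trials(session$schedule)
  ), class = "label_quality")
}

#' @export
print.label_quality <- function(x, ...) {
  cat(sprintf(paste0("<label_quality %s> coupling %.2f%% drift %.2f%% | ",
                     "mag %.2f +/- %.2f%% | timing %.1f (|%.1f|) +/- %.1f ms",
                     " | RMSE %.4f (%d trials)\n"),
              x$paradigm, x$coupling_pct, x$drift_pct, x$mag_err_mean_pct,
              x$mag_err_disp_pct, x$timing_err_mean_ms,
              x$timing_err_abs_mean_ms, x$timing_err_disp_ms, x$rmse,
              x$n_trials))
  invisible(x)
}

#' Label-quality table for a cohort, both paradigms
#'
#' @param cohort List of `session_data` from [simulate_cohort()].
#' @param paradigms Paradigms to evaluate.
#' @param ... Passed to [label_quality_report()].
#' @return Data frame, one row per participant x paradigm.
#' @export
cohort_label_quality <- function(cohort, paradigms = c("mimic", "mirror"),
                                 ...) {
  rows <- list()
  for (p in seq_along(cohort)) {
    for (par in paradigms) {
      r <- label_quality_report(cohort[[p]], par, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = cohort[[p]]$schedule$session_id, paradigm = par,
        coupling_pct = r$coupling_pct, drift_pct = r$drift_pct,
        mag_err_mean_pct = r$mag_err_mean_pct,
        mag_err_disp_pct = r$mag_err_disp_pct,
        timing_err_mean_ms = r$timing_err_mean_ms,
        timing_err_abs_mean_ms = r$timing_err_abs_mean_ms,
        timing_err_disp_ms = r$timing_err_disp_ms,
        rmse = r$rmse, align_lag_s = r$align_lag_s,
        n_trials = r$n_trials, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
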