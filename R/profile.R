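#' Kinematic trace container
#'
#' A time x 8 matrix of normalized joint angles in [-1, 1] sampled at `rate`
#' Hz, with per-trial boundary indices. Boundaries are half-open sample
#' ranges: the movement segment of trial i is `[onset, move_end)` and its
#' trailing rest interval is `[move_end, end)`.
#'
#' @param values Numeric matrix, time x 8.
#' @param rate Sampling rate in Hz.
#' @param boundaries Integer matrix with columns `start`, `onset`,
#'   `move_end`, `end` (1-based sample indices), one row per trial; or NULL.
#' @return A `kinematic_trace` object.
#' @export
kinematic_trace <- function(values, rate, boundaries = NULL) {
  values <- as.matrix(values)
  if (!is.null(boundaries)) {
    boundaries <- as.matrix(boundaries)
    stopifnot(all(c("start", "onset", "move_end", "end") %in% colnames(boundaries)))
    if (is.unsorted(boundaries[, "start"]))
      stop("trial boundaries must be sorted")
    if (any(boundaries[, "end"] > nrow(values) + 1L))
      stop("trial boundaries exceed trace length")
  }
  structure(list(values = values, rate = rate, boundaries = boundaries),
            class = "kinematic_trace")
}

#' @export
print.kinematic_trace <- function(x, ...) {
  cat(sprintf("<kinematic_trace> %d samples x %d DOFs @ %g Hz (%.1f s), %s trials\n",
              nrow(x$values), ncol(x$values), x$rate,
              nrow(x$values) / x$rate,
              if (is.null(x$boundaries)) "no" else nrow(x$boundaries)))
  invisible(x)
}

#' Trapezoidal movement profile
#'
#' Normalized deviation at time `u` (seconds from movement onset): a linear
#' ramp from 0 to 1 over `ramp_s`, a hold at 1 for `hold_s`, and a linear
#' return to 0 over `ramp_s`. Zero outside `[0, 2*ramp_s + hold_s]`.
#'
#' @param u Numeric vector of times relative to movement onset, seconds.
#' @param ramp_s,hold_s Segment durations, seconds.
#' @return Numeric vector of profile values in [0, 1].
#' @export
trapezoid_profile <- function(u, ramp_s = 0.7, hold_s = 0.1) {
  up <- pmin(pmax(u / ramp_s, 0), 1)
  down <- pmin(pmax((2 * ramp_s + hold_s - u) / ramp_s, 0), 1)
  pmin(up, down)
}

#' Preprogrammed virtual-hand kinematics for a schedule
#'
#' Each trial moves its target DOFs along a signed trapezoid (ramp to the
#' full deviation +/-1, hold, ramp back) while all non-target DOFs and all
#' intertrial rest samples are exactly 0.
#'
#' @param schedule A [build_schedule()] result.
#' @return A [kinematic_trace()] with populated trial boundaries.
#' @export
preprogrammed_profile <- function(schedule) {
  tm <- schedule$timing
  rate <- tm$kinematic_rate_hz
  spt <- trial_duration_s(tm) * rate
  if (abs(spt - round(spt)) > 1e-9)
    stop("trial duration must be an integer number of kinematic samples")
  spt <- as.integer(round(spt))
  move_n <- as.integer(round((2 * tm$ramp_s + tm$hold_s) * rate))
  nt <- n_trials(schedule)
  vals <- matrix(0, nrow = nt * spt, ncol = N_DOF,
                 dimnames = list(NULL, dof_names()))
  u <- (seq_len(spt) - 1) / rate
  trap <- trapezoid_profile(u, tm$ramp_s, tm$hold_s)
  for (i in seq_len(nt)) {
    mv <- schedule$movements[[schedule$trials$movement_id[i]]]
    idx <- (i - 1L) * spt + seq_len(spt)
    for (j in seq_along(mv$target_dofs))
      vals[idx, mv$target_dofs[j]] <- mv$direction[j] * trap
  }
  starts <- (seq_len(nt) - 1L) * spt + 1L
  boundaries <- cbind(start = starts, onset = starts,
                      move_end = starts + move_n, end = starts + spt)
  kinematic_trace(vals, rate, boundaries)
}
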