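#' Simulate one participant-session of bilateral training data
#'
#' Builds the preprogrammed virtual-hand trace for `schedule`, then derives
#' the ground-truth (right) hand, the contralateral mirror (left) hand, and
#' surrogate raw EMG. Per trial, the ground-truth target profile is scaled by
#' `1 + magnitude error`, delayed by a lag drawn from a positive-truncated
#' normal, and leaked into non-target DOFs through the coupling matrix; a
#' per-rest-interval random-walk offset (resting drift) is added to all DOFs;
#' everything is clipped to [-1, 1] last. The mirror hand tracks the ground
#' truth with a zero-mean two-sided per-trial timing jitter and a small
#' multiplicative magnitude noise.
#'
#' Random draws are consumed in a fixed, documented order (per-trial
#' magnitude errors, per-trial lags, per-interval drift steps, per-trial
#' mirror jitters, per-trial mirror magnitude noises, then EMG noise), so a
#' given `(schedule, params)` pair is bit-reproducible.
#'
#' @param schedule A [build_schedule()] result.
#' @param params A [participant_params()] object.
#' @param with_emg If FALSE, skip EMG synthesis (the kinematic draws are
#'   unaffected); `session$emg` is then NULL.
#' @return A `session_data` list: `schedule`, `virtual`, `truth`, `mirror`
#'   ([kinematic_trace()]s), `emg` ([raw_emg()] or NULL) and `params`.
#' @export
simulate_participant <- function(schedule, params, with_emg = TRUE) {
  tm <- schedule$timing
  rate <- tm$kinematic_rate_hz
  virtual <- preprogrammed_profile(schedule)
  nt <- n_trials(schedule)
  bounds <- virtual$boundaries
  spt <- bounds[1, "end"] - bounds[1, "start"]

  set.seed(params$seed)
  eps <- stats::rnorm(nt, params$mimic_mag_err_mean, params$mimic_mag_err_sd)
  lag <- rtruncnorm_pos(nt, params$mimic_lag_mean_s, params$mimic_lag_sd_s)
  steps <- matrix(stats::rnorm(nt * N_DOF, 0, params$drift_step_sd), nt, N_DOF)
  jitter <- stats::rnorm(nt, 0, params$mirror_jitter_sd_s)
  eta <- stats::rnorm(nt, 0, params$mirror_mag_err_sd)

  if (any(lag >= tm$intertrial_s) || any(abs(jitter) >= tm$intertrial_s))
    stop("lag or jitter magnitude exceeds the intertrial interval; ",
         "shifted movements would alias into neighbouring trials")

  u <- (seq_len(spt) - 1) / rate
  truth_vals <- matrix(0, nrow(virtual$values), N_DOF)
  # drift offsets: offset[i, ] applies to the rest interval of trial i and the
  # movement segment of trial i + 1; trial 1's movement sees a zero offset
  offsets <- matrix(0, nt, N_DOF)
  prev <- rep(0, N_DOF)
  for (i in seq_len(nt)) {
    prev <- pmin(pmax(prev + steps[i, ], -params$drift_max), params$drift_max)
    offsets[i, ] <- prev
  }
  cm <- params$coupling_matrix
  for (i in seq_len(nt)) {
    mv <- schedule$movements[[schedule$trials$movement_id[i]]]
    idx <- bounds[i, "start"]:(bounds[i, "end"] - 1L)
    contrib <- matrix(0, spt, N_DOF)
    trap_i <- trapezoid_profile(u - lag[i], tm$ramp_s, tm$hold_s)
    for (j in seq_along(mv$target_dofs)) {
      k <- mv$target_dofs[j]
      contrib[, k] <- mv$direction[j] * (1 + eps[i]) * trap_i
    }
    leak <- contrib %*% t(cm)
    leak[, mv$target_dofs] <- 0  # coupling leaks into non-target DOFs only
    off_move <- if (i == 1L) rep(0, N_DOF) else offsets[i - 1L, ]
    move_len <- bounds[i, "move_end"] - bounds[i, "start"]
    off <- rbind(matrix(off_move, move_len, N_DOF, byrow = TRUE),
                 matrix(offsets[i, ], spt - move_len, N_DOF, byrow = TRUE))
    truth_vals[idx, ] <- contrib + leak + off
  }
  truth_vals <- pmin(pmax(truth_vals, -1), 1)

  mirror_vals <- truth_vals
  tt <- (seq_len(spt) - 1) / rate
  for (i in seq_len(nt)) {
    idx <- bounds[i, "start"]:(bounds[i, "end"] - 1L)
    seg <- truth_vals[idx, , drop = FALSE]
    shifted <- apply(seg, 2, function(col)
      stats::approx(tt, col, xout = tt - jitter[i], rule = 2)$y)
    mirror_vals[idx, ] <- (1 + eta[i]) * shifted
  }
  mirror_vals <- pmin(pmax(mirror_vals, -1), 1)

  truth <- kinematic_trace(truth_vals, rate, bounds)
  mirror <- kinematic_trace(mirror_vals, rate, bounds)
  colnames(truth$values) <- colnames(mirror$values) <- dof_names()
  emg <- if (with_emg) synthesize_emg(truth, params, emg_rate = tm$emg_rate_hz)
         else NULL
  structure(list(schedule = schedule, virtual = virtual, truth = truth,
                 mirror = mirror, emg = emg, params = params),
            class = "session_data")
}

# positive-truncated normal via inverse-CDF so exactly one uniform draw is
# consumed per trial (keeps the documented draw order intact)
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  p0 <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n)
  stats::qnorm(p0 + u * (1 - p0), mean, sd)
}

#' Raw EMG container
#'
#' @param values Numeric matrix, time x channels, arbitrary amplitude units.
#' @param rate Sampling rate in Hz.
#' @return A `raw_emg` object.
#' @export
raw_emg <- function(values, rate) {
  structure(list(values = as.matrix(values), rate = rate), class = "raw_emg")
}

#' @export
print.raw_emg <- function(x, ...) {
  cat(sprintf("<raw_emg> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$rate, nrow(x$values) / x$rate))
  invisible(x)
}

#' Synthesize surrogate raw EMG from a kinematic trace
#'
#' The per-channel envelope is `e(t) = baseline + Gpos %*% max(theta, 0) +
#' Gneg %*% max(-theta, 0)`, linearly interpolated from the kinematic grid up
#' to `emg_rate`; each raw sample is the envelope times an independent
#' standard-normal draw (amplitude-modulated Gaussian noise). The expected
#' mean absolute value of the raw signal is therefore `e(t) * sqrt(2/pi)`,
#' which gives the feature pipeline a closed-form oracle.
#'
#' Uses the current RNG state; seed it (or call via
#' [simulate_participant()]) for reproducibility.
#'
#' @param trace A [kinematic_trace()] with values in [-1, 1].
#' @param params A [participant_params()] (synergy matrices and baseline).
#' @param emg_rate Output sampling rate, Hz.
#' @return A [raw_emg()] object.
#' @export
synthesize_emg <- function(trace, params, emg_rate = 1000) {
  if (any(params$synergy_gain_pos < 0) || any(params$synergy_gain_neg < 0) ||
      any(params$emg_baseline < 0))
    stop("synergy gains and baseline must be nonnegative")
  v <- trace$values
  env_kin <- pmax(v, 0) %*% t(params$synergy_gain_pos) +
    pmax(-v, 0) %*% t(params$synergy_gain_neg)
  env_kin <- sweep(env_kin, 2, params$emg_baseline, `+`)
  n_out <- as.integer(round(nrow(v) / trace$rate * emg_rate))
  t_kin <- (seq_len(nrow(v)) - 1) / trace$rate
  t_out <- (seq_len(n_out) - 1) / emg_rate
  env <- apply(env_kin, 2, function(col)
    stats::approx(t_kin, col, xout = t_out, rule = 2)$y)
  noise <- matrix(stats::rnorm(length(env)), nrow(env), ncol(env))
  raw_emg(env * noise, emg_rate)
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("<session_data '%s'> %d trials, %.1f s, EMG: %s\n",
              x$schedule$session_id, n_trials(x$schedule),
              nrow(x$truth$values) / x$truth$rate,
              if (is.null(x$emg)) "none" else
                sprintf("%d ch @ %g Hz", ncol(x$emg$values), x$emg$rate)))
  invisible(x)
}

#' Simulate a cohort of participants
#'
#' Per-participant seeds are derived reproducibly from `seed`.
#'
#' @param n_participants Cohort size.
#' @param preset Preset name passed to [participant_params()].
#' @param protocol,reps Passed to [build_schedule()].
#' @param seed Master seed.
#' @param with_emg Passed to [simulate_participant()].
#' @param params_fn Optional function(seed) returning a
#'   [participant_params()]; overrides `preset`.
#' @return List of `session_data`, one per participant.
#' @export
simulate_cohort <- function(n_participants = 7, preset = "paper_healthy",
                            protocol = "biomech", reps = 10, seed = 1,
                            with_emg = FALSE, params_fn = NULL) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  lapply(seq_len(n_participants), function(i) {
    p <- if (is.null(params_fn)) participant_params(preset = preset, seed = seeds[i])
         else params_fn(seeds[i])
    sched <- build_schedule(protocol, reps = reps,
                            session_id = sprintf("p%02d", i))
    simulate_participant(sched, p, with_emg = with_emg)
  })
}

#' Simulate the three-session offline machine-learning dataset
#'
#' One participant performing the 14-movement individuated protocol three
#' times (20 repetitions per movement per session, 840 trials total), as
#' used for the dataset-size evaluation. Each session re-seeds the generator
#' from a sub-seed so sessions differ but the whole dataset is reproducible.
#'
#' @param preset,seed,reps,with_emg See [simulate_cohort()].
#' @param n_sessions Number of sessions (default 3).
#' @return List of `session_data` of length `n_sessions`.
#' @export
simulate_ml_participant <- function(preset = "paper_healthy", seed = 1,
                                    reps = 20, n_sessions = 3,
                                    with_emg = TRUE) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)
  lapply(seq_len(n_sessions), function(s) {
    p <- participant_params(preset = preset, seed = seeds[s])
    sched <- build_schedule("ml", reps = reps, session_id = sprintf("ml%d", s))
    simulate_participant(sched, p, with_emg = with_emg)
  })
}
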