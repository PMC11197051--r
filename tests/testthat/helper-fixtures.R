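# Shared fixtures, memoised so expensive simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a 7-participant healthy cohort with EMG, both-paradigm metrics table
cohort_metrics_fixture <- function(seed) {
  memo(paste0("cohort_metrics_", seed), {
    cohort <- simulate_cohort(7, preset = "paper_healthy", seed = seed,
                              with_emg = TRUE)
    cohort_label_quality(cohort)
  })
}

# kinematics-only cohort (fast) for coupling/drift checks
cohort_kin_fixture <- function(seed) {
  memo(paste0("cohort_kin_", seed), {
    simulate_cohort(7, preset = "paper_healthy", seed = seed,
                    with_emg = FALSE)
  })
}

# single-knob 50-trial session: all noise off except the named parameter
single_knob_session <- function(knob, value, seed, reps = 50,
                                extra = list()) {
  args <- c(list(seed = seed), stats::setNames(list(value), knob), extra)
  p <- do.call(participant_params, args)
  sched <- build_schedule("biomech", reps = reps)
  sched$trials <- sched$trials[sched$trials$movement_id == "d2_flex", ,
                               drop = FALSE]
  sched$trials$trial <- seq_len(nrow(sched$trials))
  simulate_participant(sched, p, with_emg = FALSE)
}

# small three-session ml participant with reduced feature channels
ml_datasets_fixture <- function(seed = 11, reps = 4, channels = 32) {
  memo(paste0("ml_", seed, "_", reps, "_", channels), {
    sessions <- simulate_ml_participant(seed = seed, reps = reps)
    feats <- lapply(sessions, function(s)
      compute_mav_features(s$emg, max_channels = channels))
    list(
      sessions = sessions,
      mimic = build_training_dataset(sessions, "mimic", features = feats),
      mirror = build_training_dataset(sessions, "mirror", features = feats))
  })
}
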