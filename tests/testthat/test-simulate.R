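target_dofs_of_test <- function(schedule, i)
  schedule$movements[[schedule$trials$movement_id[i]]]$target_dofs

noise_free_session <- function(reps = 2, seed = 5, with_emg = FALSE) {
  p <- participant_params(preset = "noise_free", seed = seed)
  simulate_participant(build_schedule("biomech", reps = reps), p,
                       with_emg = with_emg)
}

test_that("noise-free limit: truth and mirror equal the virtual trace", {
  s <- noise_free_session()
  expect_equal(s$truth$values, s$virtual$values, ignore_attr = TRUE)
  expect_equal(s$mirror$values, s$truth$values, ignore_attr = TRUE)
})

test_that("identical seed and params give bit-identical sessions", {
  p <- participant_params(preset = "paper_healthy", seed = 99)
  sched <- build_schedule("biomech", reps = 2)
  a <- simulate_participant(sched, p, with_emg = TRUE)
  b <- simulate_participant(sched, p, with_emg = TRUE)
  expect_identical(a$truth$values, b$truth$values)
  expect_identical(a$mirror$values, b$mirror$values)
  expect_identical(a$emg$values, b$emg$values)
  # kinematic draws are unaffected by skipping EMG synthesis
  c <- simulate_participant(sched, p, with_emg = FALSE)
  expect_identical(c$truth$values, a$truth$values)
})

test_that("coupling leakage reproduces the injected fraction on one trial", {
  cm <- matrix(0, 8, 8)
  cm[4, 2] <- 0.3  # D2 flexion leaks into D4
  p <- participant_params(coupling_matrix = cm, seed = 1)
  sched <- build_schedule("biomech", reps = 1)
  s <- simulate_participant(sched, p, with_emg = FALSE)
  b <- s$truth$boundaries
  i <- which(sched$trials$movement_id == "d2_flex")
  win <- b[i, "onset"]:(b[i, "end"] - 1)
  expect_equal(max(s$truth$values[win, 4]), 0.3, tolerance = 1e-12)
  # leaked profile follows the target trapezoid exactly
  expect_equal(s$truth$values[win, 4], 0.3 * s$truth$values[win, 2],
               tolerance = 1e-12)
  # no leakage anywhere else, and none into the target
  other <- setdiff(1:8, c(2, 4))
  expect_equal(max(abs(s$truth$values[win, other])), 0)
})

test_that("values stay in the normalized range under extreme parameters", {
  p <- participant_params(preset = "paper_healthy",
                          coupling_matrix = uniform_coupling(0.9),
                          drift_step_sd = 0.2, mimic_mag_err_mean = 0.5,
                          seed = 3)
  s <- simulate_participant(build_schedule("biomech", reps = 2), p,
                            with_emg = FALSE)
  expect_true(all(abs(s$truth$values) <= 1))
  expect_true(all(abs(s$mirror$values) <= 1))
})

test_that("lags or jitters reaching the intertrial interval are rejected", {
  p <- participant_params(mimic_lag_mean_s = 1.2, seed = 1)
  expect_error(simulate_participant(build_schedule("biomech", reps = 1), p,
                                    with_emg = FALSE), "alias")
  p2 <- participant_params(mirror_jitter_sd_s = 3, seed = 1)
  expect_error(simulate_participant(build_schedule("biomech", reps = 1), p2,
                                    with_emg = FALSE), "alias")
})

test_that("mimic lag is always positive and mirror jitter two-sided", {
  p <- participant_params(mimic_lag_mean_s = 0.02, mimic_lag_sd_s = 0.05,
                          mirror_jitter_sd_s = 0.05, seed = 17)
  sched <- build_schedule("biomech", reps = 10)
  s <- simulate_participant(sched, p, with_emg = FALSE)
  b <- s$truth$boundaries
  # truth onset can never precede the virtual onset (positive lag), while
  # the mirror hand sometimes precedes and sometimes lags the truth
  first_move <- function(v, win) win[which(abs(v[win]) > 1e-9)[1]]
  lead_truth <- lead_mirror <- numeric(0)
  for (i in seq_len(nrow(b))) {
    dof <- target_dofs_of_test(s$schedule, i)
    win <- b[i, "onset"]:(b[i, "end"] - 1)
    lead_truth <- c(lead_truth,
                    first_move(s$truth$values[, dof[1]], win) -
                      first_move(s$virtual$values[, dof[1]], win))
    lead_mirror <- c(lead_mirror,
                     first_move(s$mirror$values[, dof[1]], win) -
                       first_move(s$truth$values[, dof[1]], win))
  }
  expect_true(all(lead_truth >= 0))
  expect_true(any(lead_mirror > 0) && any(lead_mirror < 0))
})

test_that("participant parameter validation enforces the invariants", {
  expect_error(participant_params(coupling_matrix = uniform_coupling(1)),
               "\\[0, 1\\)")
  bad <- uniform_coupling(0.1); diag(bad) <- 0.2
  expect_error(participant_params(coupling_matrix = bad), "diagonal")
  expect_error(participant_params(drift_step_sd = -1), "SD")
  expect_error(participant_params(synergy_gain_pos = -matrix(1, 32, 8),
                                  synergy_gain_neg = matrix(1, 32, 8)),
               "nonnegative")
  expect_error(participant_params(preset = "no_such_preset"), "preset")
})
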