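nf_session <- function(reps = 3) {
  p <- participant_params(preset = "noise_free", seed = 2)
  simulate_participant(build_schedule("biomech", reps = reps), p,
                       with_emg = FALSE)
}

test_that("all metrics are exactly zero on a noise-free session", {
  s <- nf_session()
  expect_equal(biomechanical_coupling(s), 0)
  expect_equal(rest_drift(s), 0)
  r <- label_quality_report(s, "mirror")
  expect_equal(r$mag_err_mean_pct, 0)
  expect_equal(r$mag_err_disp_pct, 0)
  expect_equal(r$timing_err_mean_ms, 0)
  expect_equal(r$timing_err_disp_ms, 0)
  expect_equal(r$rmse, 0)
  # mimic without alignment is also exact in the noise-free limit
  r2 <- label_quality_report(s, "mimic", align = FALSE)
  expect_equal(r2$rmse, 0)
})

test_that("uniform coupling is recovered by direct summation on the trace", {
  p <- participant_params(coupling_matrix = uniform_coupling(0.10), seed = 1)
  s <- simulate_participant(build_schedule("biomech", reps = 1), p,
                            with_emg = FALSE)
  got <- biomechanical_coupling(s)
  # brute force: per trial, mean |non-target values| over the movement window
  b <- s$truth$boundaries
  per_trial <- vapply(seq_len(nrow(b)), function(i) {
    mv <- s$schedule$movements[[s$schedule$trials$movement_id[i]]]
    nt <- setdiff(1:8, mv$target_dofs)
    win <- b[i, "onset"]:(b[i, "move_end"] - 1)
    mean(abs(s$truth$values[win, nt]))
  }, numeric(1))
  expect_equal(got, 100 * median(per_trial), tolerance = 1e-12)
  # and the median trial equals the leaked trapezoid's hand-computed mean:
  # 0.10 * mean over the 45 movement samples of the trapezoid (24/45)
  expect_equal(got, 100 * 0.10 * 24 / 45, tolerance = 1e-9)
})

test_that("a deterministic rest step shows up as exactly that drift", {
  s <- nf_session(reps = 3)  # 54 trials
  b <- s$truth$boundaries
  # +0.05 offset on all DOFs from the first rest interval onward
  from <- b[1, "move_end"]
  s$truth$values[from:nrow(s$truth$values), ] <-
    s$truth$values[from:nrow(s$truth$values), ] + 0.05
  expect_equal(rest_drift(s), 5, tolerance = 1e-12)
  # coupling references the drift-updated rest level, so it stays 0
  expect_equal(biomechanical_coupling(s), 0, tolerance = 1e-12)
})

test_that("a 90% movement scale yields a 10% magnitude error with zero spread", {
  s <- nf_session(reps = 2)
  labels <- kinematic_trace(0.9 * s$truth$values, s$truth$rate,
                            s$truth$boundaries)
  m <- magnitude_error_stats(labels, s$truth, s$schedule)
  expect_equal(m$mean_pct, 10, tolerance = 1e-9)
  expect_equal(m$disp_pct, 0, tolerance = 1e-9)
})

test_that("random per-trial scales match brute-force enumeration on a toy session", {
  s <- nf_session(reps = 1)
  sched <- s$schedule
  sched$trials <- sched$trials[1:5, ]
  b <- s$truth$boundaries[1:5, , drop = FALSE]
  n_keep <- b[5, "end"] - 1
  truth <- kinematic_trace(s$truth$values[1:n_keep, ], 30, b)
  set.seed(8)
  scales <- runif(5, 0.7, 1.3)
  lv <- truth$values
  for (i in 1:5) {
    win <- b[i, "start"]:(b[i, "end"] - 1)
    lv[win, ] <- pmin(pmax(scales[i] * lv[win, ], -1), 1)
  }
  labels <- kinematic_trace(lv, 30, b)
  s2 <- s; s2$schedule <- sched
  m <- magnitude_error_stats(labels, truth, sched, boundaries = b)
  expected <- 100 * abs(pmin(scales, 1) - 1)  # peaks clip at 1
  expect_equal(m$errors_pct, expected, tolerance = 1e-9)
  expect_equal(m$mean_pct, mean(expected), tolerance = 1e-9)
  expect_equal(m$disp_pct, sd(expected), tolerance = 1e-9)
})

test_that("a two-sample label delay is a 66.7 ms timing error with zero spread", {
  s <- nf_session(reps = 2)
  labels <- shift_trace_zero(s$truth, -2)  # delay by 2 samples at 30 Hz
  tim <- timing_error_stats(labels, s$truth, s$schedule)
  expect_equal(tim$mean_ms, 2000 / 30, tolerance = 1e-9)
  expect_equal(tim$disp_ms, 0, tolerance = 1e-9)
})

test_that("trace RMSE has its closed forms", {
  s <- nf_session(reps = 1)
  expect_equal(trace_rmse(s$truth, s$truth), 0)
  shifted <- kinematic_trace(s$truth$values + 0.1, 30, s$truth$boundaries)
  expect_equal(trace_rmse(shifted, s$truth), 0.1, tolerance = 1e-12)
  bad <- kinematic_trace(s$truth$values[1:10, ], 30)
  expect_error(trace_rmse(bad, s$truth), "shape")
})

test_that("the report equals the individually invoked operations", {
  p <- participant_params(preset = "paper_healthy", seed = 31)
  s <- simulate_participant(build_schedule("biomech", reps = 2), p,
                            with_emg = FALSE)
  r <- label_quality_report(s, "mirror")
  m <- magnitude_error_stats(s$mirror, s$truth, s$schedule)
  tim <- timing_error_stats(s$mirror, s$truth, s$schedule)
  expect_equal(r$mag_err_mean_pct, m$mean_pct)
  expect_equal(r$mag_err_disp_pct, m$disp_pct)
  expect_equal(r$timing_err_mean_ms, tim$mean_ms)
  expect_equal(r$timing_err_disp_ms, tim$disp_ms)
  expect_equal(r$coupling_pct, biomechanical_coupling(s))
  expect_equal(r$drift_pct, rest_drift(s))
  expect_equal(r$rmse, trace_rmse(s$mirror, s$truth))
})

test_that("coupling and drift do not depend on the evaluated paradigm", {
  p <- participant_params(preset = "paper_healthy", seed = 13)
  s <- simulate_participant(build_schedule("biomech", reps = 2), p,
                            with_emg = FALSE)
  r1 <- label_quality_report(s, "mirror")
  r2 <- label_quality_report(s, "mimic", align = FALSE)
  expect_equal(r1$coupling_pct, r2$coupling_pct)
  expect_equal(r1$drift_pct, r2$drift_pct)
})

test_that("magnitude error is invariant under a common shift; timing shifts additively", {
  p <- participant_params(mimic_mag_err_mean = -0.15, seed = 5)
  s <- simulate_participant(build_schedule("biomech", reps = 2), p,
                            with_emg = FALSE)
  m0 <- magnitude_error_stats(s$virtual, s$truth, s$schedule)
  # shift both traces by the same 3 samples
  lab_s <- shift_trace_zero(s$virtual, -3)
  tru_s <- shift_trace_zero(s$truth, -3)
  m1 <- magnitude_error_stats(lab_s, tru_s, s$schedule,
                              boundaries = s$truth$boundaries)
  expect_equal(m1$mean_pct, m0$mean_pct, tolerance = 1e-9)
  t0 <- timing_error_stats(s$virtual, s$truth, s$schedule)
  t1 <- timing_error_stats(shift_trace_zero(s$virtual, -3), s$truth,
                           s$schedule)
  expect_equal(t1$mean_ms, t0$mean_ms + 3000 / 30, tolerance = 1e-9)
})
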