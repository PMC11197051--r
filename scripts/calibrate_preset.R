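#!/usr/bin/env Rscript
# One-off calibration of the `paper_healthy` preset (documented, re-runnable).
#
# Order: (1) set the uniform coupling fraction so the cohort-mean
# biomechanical-coupling metric of a 7-participant simulated cohort lands on
# 11.43% of full normalized deviation; (2) with coupling fixed, set the
# drift random-walk step SD so the cohort-mean rest-drift metric lands on
# 7.07%; magnitude/timing parameters are set analytically afterwards (see
# the methods vignette) and are not touched here. Both metrics are close to
# linear in their knob over this range, so one secant step from two probe
# values suffices; the result is frozen into inst/presets/paper_healthy.yaml.
#
# Usage: Rscript scripts/calibrate_preset.R

library(myolabel)

target_coupling <- 11.43
target_drift <- 7.07

cohort_means <- function(coupling_value, drift_sd, n = 7, seed = 101) {
  cohort <- simulate_cohort(
    n, protocol = "biomech", reps = 10, seed = seed, with_emg = FALSE,
    params_fn = function(s) participant_params(
      preset = "paper_healthy", seed = s,
      coupling_matrix = uniform_coupling(coupling_value),
      drift_step_sd = drift_sd))
  c(coupling = mean(vapply(cohort, biomechanical_coupling, numeric(1))),
    drift = mean(vapply(cohort, rest_drift, numeric(1))))
}

secant <- function(f, x1, x2, target) {
  y1 <- f(x1); y2 <- f(x2)
  x1 + (target - y1) * (x2 - x1) / (y2 - y1)
}

cat("calibrating coupling...\n")
cal_c <- secant(function(c) cohort_means(c, 0.009)["coupling"],
                0.20, 0.28, target_coupling)
cat(sprintf("  coupling fraction = %.4f\n", cal_c))

cat("calibrating drift step SD (coupling fixed)...\n")
cal_d <- secant(function(d) cohort_means(cal_c, d)["drift"],
                0.008, 0.012, target_drift)
cat(sprintf("  drift step SD = %.5f\n", cal_d))

chk <- cohort_means(cal_c, cal_d)
cat(sprintf("check at calibrated values: coupling %.2f%% (target %.2f), drift %.2f%% (target %.2f)\n",
            chk["coupling"], target_coupling, chk["drift"], target_drift))
chk2 <- cohort_means(cal_c, cal_d, seed = 2024)
cat(sprintf("independent-seed check:     coupling %.2f%%, drift %.2f%%\n",
            chk2["coupling"], chk2["drift"]))
cat("freeze these into inst/presets/paper_healthy.yaml\n")
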