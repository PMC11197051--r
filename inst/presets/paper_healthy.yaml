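name: paper_healthy
description: >
  Healthy-cohort preset. Coupling and drift were calibrated (see
  scripts/calibrate_preset.R) so that the cohort-mean biomechanical-coupling
  and rest-drift metrics of a 7-participant simulated cohort land on the
  reference cohort values (11.43% and 7.07% of full normalized deviation);
  magnitude and timing parameters were then set to reproduce the sign
  pattern of the mimic/mirror accuracy-precision comparison.
coupling:
  type: uniform
  value: 0.2458
drift_step_sd: 0.0094
drift_max: 0.25
mimic_lag_mean_s: 0.115
mimic_lag_sd_s: 0.005
mirror_jitter_sd_s: 0.015
mimic_mag_err_mean: -0.11
mimic_mag_err_sd: 0.05
mirror_mag_err_sd: 0.096
synergy:
  type: banded
  n_channels: 32
  gain: 1.0
  crosstalk: 0.1
  baseline: 0.05
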