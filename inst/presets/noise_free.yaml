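name: noise_free
description: >
  All noise terms zero: the ground-truth hand reproduces the preprogrammed
  kinematics exactly and the mirror hand reproduces the ground truth exactly.
  Useful as a degenerate reference; every label-quality metric is 0.
coupling:
  type: uniform
  value: 0.0
drift_step_sd: 0.0
drift_max: 0.25
mimic_lag_mean_s: 0.0
mimic_lag_sd_s: 0.0
mirror_jitter_sd_s: 0.0
mimic_mag_err_mean: 0.0
mimic_mag_err_sd: 0.0
mirror_mag_err_sd: 0.0
synergy:
  type: banded
  n_channels: 32
  gain: 1.0
  crosstalk: 0.1
  baseline: 0.05
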