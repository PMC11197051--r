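Package: myolabel
Title: Training-Label Quality and Decoder Evaluation for Myoelectric Regression Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates bilateral mimic/mirror training sessions for surface-EMG
    (sEMG) regression control of a multi-articulate hand: preprogrammed
    trapezoidal virtual-hand kinematics, an imperfect ground-truth hand
    (reaction lag, magnitude error, biomechanical coupling, resting-position
    drift), a contralateral mirror hand, and surrogate 32-channel raw EMG.
    Provides the 528-channel mean-absolute-value (MAV) feature pipeline with
    differential electrode pairs, cross-correlation label alignment,
    training-label quality metrics (coupling, drift, spatial/temporal accuracy
    and precision, RMSE), a linear Kalman decoder with modified-Kalman
    threshold/rescale post-processing, a windowed convolutional regressor, and
    a shuffled k-fold dataset-size evaluation with cohort statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
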