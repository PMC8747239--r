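Package: gaitlstm
Title: Multi-Joint Sagittal Angle Estimation from a Single Low-Frequency Shank IMU
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates hip, knee and ankle sagittal-plane joint angles during
    overground walking from a single 23 Hz shank-mounted inertial measurement
    unit. Provides a synthetic gait cohort simulator (Fourier-series joint-angle
    templates with planar forward kinematics of the leg), signal conditioning
    (zero-phase Butterworth low-pass, median smoothing, per-cycle label
    resampling, min-max normalisation), Pearson-correlation filter feature
    selection, an LSTM sequence regressor trained with a weighted three-joint
    mean-squared-error loss, and evaluation under within-one-subject,
    intra-subject and inter-subject cross-validation with RMSE, NRMSE and R2
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
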