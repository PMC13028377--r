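Package: vaultkin
Title: Run-Up and Take-Off Kinematics for Pole Vault Method Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for multi-camera kinematic analysis of the
    pole vault run-up and take-off, built for comparing a markerless tracking
    method against manually digitised reference data. Provides 11-parameter
    direct linear transformation (DLT) camera calibration and least-squares
    3D reconstruction, zero-lag Butterworth filtering, a de Leva segmental
    model for whole-body centre-of-mass and sagittal joint angles, rule-based
    gait event detection, extraction of the standard run-up/take-off variable
    set, and a two-method agreement battery (Bland-Altman bias and limits of
    agreement, RMSE, ICC(3,1), and waveform coefficient of multiple
    determination). A synthetic vaulter generator emulating a four-camera
    100 Hz competition capture makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
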