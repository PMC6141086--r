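Package: hipforce
Title: Hip Contact Force Prediction from Gait by Inverse Dynamics and
    Static-Optimization Muscle Recruitment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An open implementation of a lower-limb musculoskeletal analysis
    pipeline for gait: marker-based inverse kinematics with segment-length
    calibration and a hip-joint-centre regression constraint, recursive
    Newton-Euler inverse dynamics, muscle paths with via points and
    single-cylinder wrapping, tendon-excursion moment arms, static
    optimization of muscle recruitment minimizing the sum of cubed
    activations, per-muscle decomposition of the hip contact force from the
    limb free-body balance, flagging of anatomically suspect muscle
    geometry, and validation metrics (component/total/stance/swing RMSE,
    activation on-off timing).  Ships a synthetic gait generator and toy
    lower-limb models so the full pipeline is testable without external
    motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
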