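Package: parattc
Title: Time-to-Contact Estimation for 3D Parabolic Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying monocular time-to-contact (TTC) estimation of
    balls on three-dimensional parabolic flights. Provides closed-form
    projectile kinematics in an observer-centred frame, projection into the
    monocular optic variables (angular size, elevation angle and its rate of
    change, azimuth), the gravity-and-size (GS) heuristic TTC predictor with
    its privileged zero-error time points, an inverse designer that tailors
    trajectories to be accurately predictable at prescribed fractions of
    flight time, a synthetic-observer generator producing trial-level
    behavioral data for an occluded interception-timing task, and a complete
    statistical pipeline (IQR outlier filtering, random-intercept linear
    mixed models with likelihood-ratio tests, Deming errors-in-variables
    regression, Weber-fraction cue discriminability, and performance
    metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
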