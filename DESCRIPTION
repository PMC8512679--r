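Package: gaittorque
Title: Sagittal Joint Torque Prediction from Statistically Estimated Ground
    Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable pipeline for predicting sagittal lower-limb joint
    torques during the stance phase of gait when ground reaction forces (GRF)
    and centres of pressure (COP) are not measured but estimated
    statistically. Features are selected by regression neighbourhood
    component analysis, per-channel single-hidden-layer neural networks
    trained with Levenberg-Marquardt updates estimate GRF/COP, and torques
    are computed by planar Newton-Euler inverse dynamics and by a hybrid
    EMG-informed neuromusculoskeletal model built on Hill-type musculotendon
    units. A seeded synthetic stance-phase gait generator provides
    dynamically consistent trials so that every stage is testable without
    laboratory data, and an evaluation layer crosses estimated/measured
    input conditions with both torque models and applies nonparametric
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lhs,
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
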