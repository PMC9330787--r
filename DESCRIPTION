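Package: turnintent
Title: Decoding Turning Intention During Walking from EEG Covariance Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An asynchronous brain-machine-interface analysis pipeline that
    discriminates monotonous walking from the intention to turn using EEG
    spatial covariance matrices classified on the Riemannian manifold of
    symmetric positive-definite matrices. Includes IMU-based labeling of the
    physical turn instant from back-worn orientation traces, adaptive
    H-infinity ocular-artifact filtering, artifact subspace reconstruction
    (ASR), causal order-2 band-pass filtering, minimum-distance-to-mean and
    tangent-space classifiers, leave-one-trial-out cross-validation with
    chance-level filtering, and causal pseudo-online / two-phase online replay
    evaluation (true positives, false positives per minute). A synthetic
    session generator emulates the statistical structure the pipeline assumes
    so every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    e1071,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
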