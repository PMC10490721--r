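Package: dysvox
Title: Dyspnea Severity Estimation from Controlled Vocalizations in
    Human-Robot Interaction Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for estimating dyspnea
    severity (mMRC scale, classes 0-3) from controlled vocalizations
    captured by a 4-microphone linear array on a robot head. Provides a
    synthetic vocalization corpus generator with class-dependent phonation,
    pause and breath-noise structure; an acoustic scene simulator
    (image-source room impulse responses, robot and environmental noise,
    static and rotating-head capture); delay-and-sum and MVDR beamforming;
    Mel/log-spectral and F0-based feature extraction; per-phonetization
    neural-network classifiers trained with a speaker-disjoint 9-fold
    double-validation protocol; and a multi-level softmax fusion hierarchy
    with accuracy and binary AUC evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
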