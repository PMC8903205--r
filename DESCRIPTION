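Package: larynxsim
Title: Muscle-Activation-Controlled Simulation of Voice Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fiber-gel vocal fold simulator controlled by intrinsic
    laryngeal muscle activations. Cricothyroid and thyroarytenoid
    activation levels (with lateral cricoarytenoid/interarytenoid
    adduction and lung pressure set by empirical constraint rules) are
    mapped to quasi-static vocal fold posture, layered fiber stresses, a
    flow-induced self-sustained oscillation of a layered finite-element
    fold coupled to a wave-reflection vocal tract, and a radiated oral
    pressure signal. Acoustic features (fundamental frequency, sound
    pressure level, normalized spectral centroid, approximate entropy)
    and postural features (length, per-layer fiber stress) are extracted
    per run and assembled into muscle activation maps over the TA-CT
    activation grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
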