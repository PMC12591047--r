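Package: morphspec
Title: Hyperspectral Colour Congruence and Predation-Trial Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how well artificial prey models reproduce
    the colouration of live animals, and for analysing predator behavioural
    trials against those models. The colour arm calibrates hyperspectral
    reflectance cubes against an 18% grey card (between-day gain correction,
    relative reflectance, Gaussian spectral smoothing), clusters pixel spectra
    with a full-covariance Gaussian mixture fitted by expectation-maximisation
    with AIC elbow model selection, and evaluates cluster-centroid colours
    under tetrachromatic avian and lacertid visual systems using the
    receptor-noise-limited model in just-noticeable-difference (JND) units.
    The behavioural arm scores right-censored alert and attack latencies from
    trial event logs and provides from-scratch survival inference:
    Kaplan-Meier curves with Greenwood confidence intervals, Cox proportional
    hazards with Efron tie handling, and Schoenfeld-residual proportional
    hazards diagnostics. Synthetic-data generators for both arms make every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma,
    vegan
Suggests:
    testthat (>= 3.0.0),
    survival,
    mclust,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
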