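Package: nirsphysio
Title: Systemic Physiology Correction and ROC Benchmarking for fNIRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for removing systemic physiological contamination
    (cardiac, respiratory and Mayer-wave oscillations, slow vascular
    drifts) from functional near-infrared spectroscopy (fNIRS)
    recordings, and for quantifying how well each correction strategy
    preserves statistical inference.  Implements spatial PCA and
    baseline-PCA prefilters, short-separation (SS) channel prefilters
    (unconstrained projection and image-reconstruction variants), and
    general linear model solvers including ordinary least squares, a
    robust autoregressively prewhitened solver (AR-IRLS), and a
    mixed-effects AR-IRLS variant that pools the SS regressor variance
    across channels.  A semisynthetic simulation engine generates
    resting and breath-hold scans with realistic serially correlated
    noise, and an ROC harness measures sensitivity, specificity,
    partial AUC and type-I error calibration of any pipeline
    combination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
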