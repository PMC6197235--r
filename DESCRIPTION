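Package: attnaxes
Title: Population Attention-Axis Analysis for Visual Cortical Spiking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating anticipatory and stimulus-evoked attention
    states from simultaneously recorded spiking populations in a cued
    change-detection task. Implements cross-validated difference-of-means
    attention axes with Gram-Schmidt orthogonalization between pre-stimulus
    and post-stimulus epochs, linkage of single-interval axis projections to
    detection behavior (quintile performance maps, d-prime), and a two-step
    time-resolved variance-accounted-for regression of population stimulus
    responses onto attention estimates with an autocorrelation-calibrated
    run-length multiple-comparisons correction. Includes an inhomogeneous
    Poisson session simulator that emulates the block-cued two-location task
    so every stage can be exercised without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    nortest,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
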