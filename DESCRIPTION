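Package: beamtune
Title: Photon Beam Model Commissioning for MLC-Based Treatment Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tuning the four MLC/source parameters of a photon
    treatment-planning beam model (effective target spot sizes sigma_X and
    sigma_Y, dosimetric leaf gap, MLC transmission): 20-80% penumbra
    extraction and spot-size tuning on scanned profiles, dosimetric leaf gap
    tuning on asynchronous oscillating sweeping gap (aOSG) point doses,
    classic sweeping-gap and transmission estimators, a Taguchi L27 design of
    experiments with ANOVA to rank parameter influence on small-field output
    factors, and a global gamma-index comparison of 2D dose planes with
    tolerance and action-limit verdicts. A closed-form synthetic dose engine
    emulates both the linac and the planning system so that every tuning
    stage can be exercised against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
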