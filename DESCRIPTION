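Package: chemosignal
Title: Quantitative Analysis of Bacterial Chemotaxis Signaling Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement pipelines for three assays of Escherichia coli
    chemotaxis signaling: flagellar-motor rotation analysis from bead-assay
    trajectories (CW bias, reversal rate, pre/post-stimulus comparison),
    three-channel E-FRET kinase-activity analysis with bi-exponential
    photobleaching correction and per-cell min-max normalization, and
    3D localization of cells inside swarm colonies from defocused
    diffraction-ring diameters. Each pipeline is paired with a seeded
    forward model (two-state switching motor, step-stimulus kinase with
    adaptation and channel cross-talk, linear ring-diameter calibration
    and ring-image renderer) so every estimator can be validated against
    known ground truth without real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
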