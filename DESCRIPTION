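Package: spheroidArray
Title: Quantitative Image Analysis for Droplet Trapping Array Spheroid Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for 3D tumor spheroids cultured
    in microfluidic droplet trapping arrays. Detects and masks the circular
    traps of a device image, segments the spheroid inside each trap from
    brightfield microscopy, computes per-spheroid morphometrics (pixel area,
    equivalent-circle diameter, circularity), links traps across imaging
    days into growth tracks, classifies growth and estimates the minimum
    encapsulated-cell count required for growth, quantifies per-spheroid
    fluorescence for proliferation (Ki-67) and viability (live/dead)
    readouts, and reports one-way ANOVA with Fisher LSD pairwise
    comparisons. Ships a synthetic scene generator with full ground truth
    (trap layouts, Poisson cell loading, gated growth, condition-dependent
    fluorescence) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
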