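Package: xylemflow
Title: Micro-PIV, Xylem Vessel Morphometry and Contrast-Enhanced MRI
    Analysis of Stem Water Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative imaging pipeline for water transport in the
    grass stem vascular system and its microfluidic analogues. Provides a
    multipass window-deformation particle image velocimetry (micro-PIV)
    engine with three-point Gaussian subpixel peak fitting and two-stage
    vector validation; label-image morphometry of xylem vessel cross
    sections including Crofton perimeter, hydraulic diameter, moment-based
    ellipse fitting and concentric ring assignment; normalization and
    classification of contrast-enhanced MRI slice time-series; the
    hydraulic scaling mathematics (mean velocity, Reynolds number,
    Reynolds-similarity matching to a Y-junction chip, and the analytic
    rectangular-duct laminar profile); and seeded synthetic-data
    generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
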