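Package: iosimap
Title: Intrinsic Optical Signal Imaging Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for widefield intrinsic optical signal imaging
    (IOSI) of cortex. Computes trial-averaged fractional reflectance change
    (delta-R/R) maps from multi-page TIFF movie stacks, extracts binary
    activation maps by z-score or percent-of-peak thresholding within a
    cranial-window mask, quantifies map geometry (area, moment-matched
    ellipse, center displacement) and map plasticity (trial accumulation
    curves, MANOVA on displacements, paired area comparisons), and provides
    a seeded synthetic phantom generator with closed-form ground truth so
    every pipeline stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    tiff,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
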