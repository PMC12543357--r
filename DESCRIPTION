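Package: morphmark
Title: Automated Morphometric Landmarking for Standardized Specimen Images
Version: 0.1.0
Authors@R:
    person("Morphmark", "Developers", email = "morphmark@example.org",
           role = c("aut", "cre"))
Description: Headless pipeline for machine-learning morphometric landmarking
    of standardized specimen photographs. Reads and writes landmark
    annotations in the image/box/part XML dialect, trains a gradient-boosted
    cascade-of-regression-trees shape predictor with cross-validated
    hyperparameter search, applies trained models to unseen images, converts
    pixel measurements to metric units via Hough-transform scale-bar
    detection, and exports predicted landmarks and inter-landmark lengths as
    CSV. Ships a deterministic synthetic fish-image generator with exact
    landmark ground truth so the full pipeline is testable without any
    external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
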