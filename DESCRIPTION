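Package: fnirsnet
Title: Thresholded Correlation Networks and Efficiency Analysis for fNIRS
    Hemoglobin Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of functional near-infrared spectroscopy
    (fNIRS) hemoglobin time series as thresholded binary correlation networks.
    Provides modified Beer-Lambert forward and inverse conversion between
    optical density and chromophore concentration changes, automated sharp-change
    artifact detection and excision, zero-phase Butterworth band-pass filtering,
    construction of binarized Pearson connectivity graphs over a threshold grid,
    global and local network efficiency, bivariate and partial correlation of
    efficiency with age and parent-rated autistic-behavior severity, K-means
    subtyping on efficiency features, and a synthetic cohort generator with
    planted ground-truth connectivity for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
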