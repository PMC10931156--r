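Package: ripenose
Title: Colorimetric Sensor Array Simulation and Analysis for Fruit Ripeness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for artificial-olfactory fruit
    ripeness assessment with 5 x 5 colorimetric sensor arrays. Generates
    seeded synthetic membrane images (25 cross-reactive dyes, saturating
    dose-response to nine fruit volatiles, variable illumination and
    geometry), extracts calibrated per-spot RGB differentials and Euclidean
    distance (ED) responses, estimates limits of detection by the blank
    mean + 3 sigma rule, clusters gas fingerprints with Ward-linkage
    hierarchical clustering, classifies ripeness by ED reference ranges,
    and trains a dense-block convolutional network with spatial pyramid
    pooling for ten-class ripeness recognition, including Grad-CAM
    interpretation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
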