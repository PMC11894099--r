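Package: nucleodyn
Title: Nuclear Shape Dynamics and Squeezing Analysis for Confined Cell
    Migration Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies nuclear plasticity of migrating immune cells in
    time-lapse fluorescence microscopy. Provides a synthetic-movie
    generator with known ground truth, trainable pixel classification and
    3D nuclear segmentation, nearest-neighbour tracking with gap closing,
    moment-based shape factor and Feret measurements on 2D projections,
    threshold-crossing squeezing-event statistics, migration summaries
    standardised to a fixed time window, spatial shape-factor heatmaps,
    fluorescence intensity normalisation (lamina rim intensities, lamin
    stoichiometry ratios, 3D nuclear means, phagosome counts), and vessel
    diameter dynamics during nuclear transit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
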