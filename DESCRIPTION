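Package: stratiforest
Title: Pixel-Based Forest Stratification and Two-Phase Inventory Design
Version: 0.1.0
Authors@R: person("Forest", "Biometrics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for area-based forest inventory from gridded remote-sensing
    layers (canopy height model, digital elevation model, multiband optical
    imagery) and variable-radius prism plots. Summarizes layers to an analysis
    grid, segments tree crowns from the canopy height model by watershed
    flooding, reduces image feature blocks with principal components, screens
    predictors with the Lasso and fits log-linear basal-area and stem-density
    models plus a logistic conifer-share model, stratifies the landscape by
    exact optimal one-dimensional binning of a basal-area by canopy-height
    volume proxy with a minimum-stratum-area merge, allocates a second-phase
    sample by Neyman allocation, computes post-stratified estimates with
    90 percent accuracy statistics, and selects an optimal grid-cell size by
    exhaustive lowest-BIC model search over concentric circular extractions.
    Includes a synthetic-landscape simulator (Gaussian random fields, stem
    maps, crowns, prism cruising) so the whole pipeline is testable without
    proprietary flight or field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
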