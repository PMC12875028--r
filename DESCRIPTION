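Package: mpevents
Title: Simulation, Detection and Deep Classification of Mass Photometry Landing Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for single-molecule mass photometry image analysis: simulation of
    landing-assay movies with optimal and suboptimal binding dynamics (binders,
    unbinders, neighbors, rollers, wobblers), ratiometric differential processing,
    point-spread-function template fitting and contrast-to-mass calibration, a 3D
    convolutional residual network that classifies spatiotemporal event thumbnails,
    and mass-histogram analytics (FWHM resolving power, valley-to-peak ratios,
    ROC/AUC, precision/recall) to quantify the gain from selective event filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    pROC
Config/testthat/edition: 3
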