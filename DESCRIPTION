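Package: residuemap
Title: Multi-Scale Wavelet Feature Fusion for Crop Residue Cover Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pixel-classification toolkit for mapping crop residue cover
    types in high-resolution multispectral imagery. Builds per-pixel
    multi-scale texture features by compressing sliding neighbourhood
    windows of the first principal component with a multi-level separable
    wavelet filter bank (db3, periodized) and max-absolute coefficient
    fusion, ranks features by random-forest Gini importance, trains naive
    Bayes, random forest, support vector machine and one-dimensional
    convolutional neural network classifiers (with an optional channel
    attention module), post-processes categorical maps by connected-domain
    calibration, and assesses accuracy with confusion matrices, overall
    accuracy and Cohen's kappa. Includes a synthetic scene generator that
    emulates the striped, homogeneous and speckled residue textures of
    harvested corn fields so the full pipeline can be exercised without
    satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tiff,
    jsonlite,
    yaml,
    ranger,
    e1071,
    igraph,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
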