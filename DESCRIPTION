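Package: cesmrad
Title: Radiomic Texture Analysis and Lesion Classification for
    Contrast-Enhanced Spectral Mammography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A computer-aided diagnosis (CADx) pipeline for paired
    low-energy/recombined contrast-enhanced spectral mammography (CESM)
    lesion regions of interest. Extracts 464 radiomic features in five
    sets (first-order statistics, keypoint counts, Sobel-gradient
    statistics, two-level Haar wavelet statistics, and gray-level
    co-occurrence matrix texture descriptors), reduces each set by
    correlation-matrix principal component analysis with an
    explained-variance retention criterion, and selects principal
    component subsets by greedy forward search that scores candidate
    models with three classifiers (random forest, Gaussian naive Bayes,
    logistic regression) under repeated stratified ten-fold
    cross-validation, reporting Youden-thresholded AUC, accuracy,
    sensitivity and specificity. Includes a seeded texture-phantom
    generator so the full pipeline runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    tiff,
    jsonlite,
    yaml,
    randomForest,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    optparse
Config/testthat/edition: 3
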