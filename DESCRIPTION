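Package: buscad
Title: Breast Ultrasound Lesion Segmentation, Shape Analysis and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis pipeline for B-mode breast ultrasound
    regions of interest. Provides a synthetic speckle-phantom generator with
    ground-truth lesion masks, speckle-oriented preprocessing (adaptive Wiener
    filter, histogram equalization, median filter), five lesion segmenters
    (region growing, k-means, fuzzy c-means, a self-organizing-map pixel
    clusterer and a two-phase level-set active contour), a ten-metric
    region-overlap evaluation suite, a bank of 24 morphological shape
    descriptors, Gaussian-overlap feature selection, and a multilayer
    perceptron benign/malignant classifier trained by online backpropagation,
    with ROC analysis and tidy accessors throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    png,
    tiff,
    e1071,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
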