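Package: fundusdr
Title: Simultaneous Detection and Segmentation of Diabetic Retinopathy Lesions in Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, CPU-scale framework for the simultaneous detection
    and segmentation of the three cardinal signs of diabetic retinopathy --
    exudates, hemorrhages and microaneurysms -- in color fundus photographs.
    Images are contrast-enhanced with a Gaussian difference transform, tiled
    into labeled square patches, and used to train a small four-block
    convolutional neural network (implemented natively in R on top of BLAS)
    whose softmax scores are swept across the image to build per-pixel,
    per-sign probability maps. Maps are binarized at ROC-optimal (Youden)
    thresholds, overlaps are resolved by probability ranking, and the result is
    cleaned by morphological closing, opening, erosion and a minimum-area rule.
    Includes a seeded synthetic fundus generator with disjoint ground-truth
    masks so every stage is testable without clinical data, patch- and
    pixel-level evaluation reports, and broom-style tidiers plus ggplot2
    autoplot methods for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
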