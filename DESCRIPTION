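Package: rfarn
Title: Retinal Vessel Segmentation with a Reverse Fusion Attention Residual Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting blood vessels in colour fundus photographs.
    Implements multiscale retinex with colour restoration (MSRCR) image
    enhancement, a reverse fusion attention residual network (residual
    encoders with atrous convolution, reverse channel and spatial attention
    modules, and a side-input image pyramid) trained on random 48x48 patches,
    sliding-window inference with overlap averaging, and a segmentation
    evaluation suite (accuracy, sensitivity, specificity, F1, Matthews
    correlation, ROC and precision-recall curves with AUC). A seed-reproducible
    synthetic fundus generator renders branching vessel trees into
    low-contrast, unevenly illuminated noisy images so the whole pipeline can
    be exercised without downloading clinical datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    tibble,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
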