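Package: glomclass
Title: Classification of Sclerotic Glomeruli in PAS-Stained Kidney Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided classification of glomeruli from Periodic
    Acid-Schiff (PAS) stained kidney biopsy images as sclerotic or
    non-sclerotic. Implements multi-colour-space segmentation of the
    Bowman's space (RGB green channel, CMYK magenta complement and CIELAB
    k-means masks fused by majority vote), morphological features (white
    area fraction and equivalent radius), multi-radial colour local binary
    pattern and Haralick grey-level co-occurrence texture features, z-score
    plus PCA feature reduction, and a cross-validated shallow neural-network
    ensemble trained by scaled conjugate gradient with MCC-driven model
    selection, ROC-based decision thresholds and hard voting. Includes a
    synthetic PAS-like glomerulus generator so the full workflow is testable
    without access to clinical slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
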