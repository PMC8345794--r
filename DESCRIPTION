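Package: stroketex
Title: Texture and Higher-Order-Spectra Radiomics for Stroke Severity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for classifying the severity of ischaemic
    stroke (LACS, PACS, TACS syndromes) from 2D grayscale brain MRI slices.
    Implements contrast-limited adaptive histogram equalisation preprocessing,
    a three-level discrete wavelet decomposition, fused gray-level
    co-occurrence (GLCM), gray-level run-length (GLRLM) and bispectral
    higher-order-spectra (HOS) texture features, ADASYN oversampling for class
    imbalance, ANOVA F-value feature ranking, sequential forward selection,
    and multi-kernel support vector machine evaluation under stratified
    10-fold cross-validation, together with the confusion-matrix metric
    arithmetic (accuracy, PPV, sensitivity, specificity, Dice) used to report
    results. A synthetic stroke-phantom generator provides class-distinct
    test images so the whole pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    e1071,
    EBImage,
    stats,
    utils,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    tiff
Config/testthat/edition: 3
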