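Package: papscreen
Title: Automated Pap-Smear Image Analysis and Cervical-Cell Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bright-field cervical cytology screening pipeline: grayscale
    conversion and contrast-limited adaptive histogram equalization, a
    trainable pixel-level scene classifier (nucleus, cytoplasm, background,
    debris) over a multi-scale filter bank, three-phase debris rejection by
    size, shape and Zernike-moment texture, extraction of 29
    nucleus/cytoplasm morphometric features, simulated-annealing wrapper
    feature selection, and a fuzzy C-means classifier defuzzified through a
    Bayesian cluster-to-class probabilistic model, with confusion-matrix
    diagnostics and ROC analysis. Includes a synthetic-data module that
    generates labelled feature tables and rendered slide images with ground
    truth, so every stage is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    grDevices,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
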