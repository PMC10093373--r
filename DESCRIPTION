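Package: dermhgso
Title: Dermoscopic Lesion Classification with an Attention CNN, Henry-Gas
    Hyperparameter Search and a Deep Belief Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, desk-scale pipeline for multi-class skin lesion
    classification from dermoscopy-style images: adaptive Wiener denoising,
    a residual convolutional feature extractor with contextual-transformer
    (CoT) attention blocks, hyperparameter tuning by the Henry Gas Solubility
    Optimization (HGSO) metaheuristic, and a stacked restricted-Boltzmann-machine
    deep belief network (DBN) classifier. Includes a synthetic lesion-image
    generator with controllable asymmetry, border irregularity, colour
    statistics and pixel noise, and a five-metric evaluation surface
    (accuracy, sensitivity, specificity, F-score, Matthews correlation) with
    per-class and macro summaries. Fitted objects have tidy(), glance()
    and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    readr,
    withr,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
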