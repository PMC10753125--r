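Package: mamseg
Title: Breast Region and Pectoral Muscle Segmentation for Digital Mammograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiclass segmentation of mammograms into background, breast and
    pectoral muscle. Provides Otsu-based mask initialization, a joint
    image/mask augmentation stack (display-window jitter, flips, rotations,
    elastic deformation, cropping, gamma, noise), a U-Net encoder-decoder
    trained with weighted cross-entropy or focal loss, patient-level data
    splitting with early stopping and hyperparameter grid search, dice-based
    evaluation with pectoral detection statistics and group comparisons, and a
    synthetic mammographic phantom generator with parameterized vendor styles
    for desk-scale experiments on raw/processed image pairs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
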