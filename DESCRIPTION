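Package: uscam
Title: Weakly-Supervised Lesion Classification and CAM Localization on
    Synthetic B-Mode Ultrasound Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a weakly-supervised breast
    ultrasound diagnosis workflow. Trains image-level-labeled convolutional
    classifiers with a global-average-pooling (GAP) head, localizes lesions
    with class activation maps (CAM), compares against fully-supervised
    ROI-cropped classifiers (manual and U-Net-automated annotation), and
    evaluates with AUC, the DeLong test for correlated ROC curves, the exact
    McNemar test, Fisher's exact test, and the Dice similarity coefficient.
    A seeded speckle-phantom generator stands in for the original study's
    private clinical images, including a machine-profile domain shift for
    external validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
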