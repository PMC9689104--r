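Package: plaqueseg
Title: Carotid Plaque Segmentation in Ultrasound with a Hybrid Atrous
    Residual U-Net
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated segmentation of carotid artery plaques in B-mode
    ultrasound images with HRU-Net, a ResNet-50 encoder / U-Net decoder
    network carrying hybrid atrous convolution (HAC) modules on its deep
    semantic layers.  Provides mask-consistent geometric augmentation
    including cropped-blood-vessel (CBV) augmentation, a class-weighted
    Dice loss, k-fold cross-validated training with softmax-averaged
    ensembling, an evaluation suite (Dice, IoU, pixel accuracy, modified
    Hausdorff distance, plaque-area error, Bland-Altman agreement, paired
    t-tests with Bonferroni correction), and a seeded synthetic
    ultrasound phantom generator for fully reproducible experiments.
    The convolutional network core (dilated convolution, batch
    normalisation, pooling, bilinear upsampling, Adam) is implemented in
    C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
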