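Package: mbffnet
Title: Multi-Branch Feature Fusion Network for Polyp Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lightweight encoder-decoder semantic segmentation for colonoscopy
    polyp images. Implements a multi-branch feature fusion network (MBFFNet)
    with a VGG16-style encoder, a stepwise decoder that fuses skip features by
    pixel-level multiplicative attention, and an hourglass feature pyramid
    branch, together with a reference concat-skip U-Net, the Dice plus
    cross-entropy training objective, segmentation evaluation statistics
    (mean IoU, precision, recall, F-score), closed-form convolutional
    parameter and FLOP accounting, paired image/mask augmentation, and a
    seeded synthetic polyp-scene generator. Forward and backward passes run
    on a compact Rcpp/RcppArmadillo convolution engine, so small models train
    on the CPU without an external deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    EBImage
Config/testthat/edition: 3
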