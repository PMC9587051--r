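Package: estrocycle
Title: Estrous Stage Classification from Vaginal Cytology with Cycle-Aware Post-Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for automated staging of the rodent estrous cycle from
    brightfield vaginal cytology images. Provides dataset manifest handling
    with curation filters, a seeded synthetic cytology generator for the four
    canonical stages (diestrus, proestrus, estrus, metestrus), the image
    preprocessing pipeline (luminance peak alignment, three-channel grayscale
    conversion, quadrisection, affine augmentation, stratified splitting and
    stage balancing), a pluggable softmax image classifier with a step-decay
    transfer-learning training schedule and a desk-scale convolutional
    backbone, softmax-margin Confidence Index computation, archetypal-cycle
    phase fitting of sequential classifications by Pearson correlation grid
    search with outlier, transition-stage, pseudopregnancy and anestrus
    flagging, and an evaluation toolkit (confusion matrices, one-vs-rest
    ROC/auROC, sensitivity-specificity cutoffs, bootstrap accuracy
    distributions, Fisher's exact comparisons, grouped k-fold out-of-sample
    testing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
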