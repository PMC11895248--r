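Package: masegnet
Title: Attention U-Net Pipeline for Retinal Microaneurysm Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for pixel-level segmentation of
    microaneurysms in colour fundus photographs: fundus-specific
    preprocessing (border crop, green-channel extraction, CLAHE, gamma
    correction, fast non-local-means denoising), non-overlapping patch
    extraction with lossless stitch-back, deterministic flip/rotate
    augmentation, a U-shaped encoder-decoder network with convolutional
    block attention (channel and spatial) and attention-gated skip
    connections trained by Adam with a plateau-halving learning-rate
    schedule, and pixel-level evaluation (accuracy, ROC/AUC, Dice, IoU).
    Includes a seeded synthetic fundus-image generator producing paired
    lesion masks so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
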