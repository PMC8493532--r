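Package: echoforge
Title: Synthetic Labeled Echocardiography from Anatomical Heart Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates synthetic, pixel-perfectly labeled 2D echocardiography
    training data from tissue-labeled 3D heart models: a parametric heart
    phantom cohort, a PCA point-distribution shape model with bounded random
    sampling, anatomical apical view-plane slicing with foreshortening
    perturbations, pseudo-ultrasound rendering (cone mask, crops, affine
    augmentation, noise, shadows, blur) with exactly aligned label masks,
    an unpaired image-to-image (CycleGAN-style) realism transform and a U-Net
    segmenter built on a self-contained CNN engine, checkpoint selection by
    label-free mask simplicity, and a full segmentation evaluation suite
    (Dice, simplicity, area bias, mean contour distance, median/MAD
    aggregation, Wilcoxon signed-rank comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
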