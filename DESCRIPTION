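Package: farmseg
Title: Instance Segmentation Networks for Farmland Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds, runs, trains and audits a family of lightweight anchor-free
    instance-segmentation networks for agricultural imagery: a YOLOv8n-seg style
    baseline extended with a stride-4 small-object detection scale, a channel-prior
    convolutional attention (CPCA) variant of the C2f block for the neck, and a
    dilated-convolution receptive-field enhancement block (RFEM/C3RFEM) after the
    SPPF stage. Includes task-aligned target assignment with a class-frequency
    weighted composite loss, mask-level mAP evaluation, a seeded synthetic
    farmland-scene generator with the matching augmentation pipeline and image
    statistics, and exact parameter/FLOP accounting for every architecture variant.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Rcpp, stats, jsonlite, yaml, png
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
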