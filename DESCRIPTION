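Package: cystseg
Title: Automated Semantic Segmentation of Kidney Cysts in T2-Weighted MR
    Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fully automated semantic segmentation of renal cysts in
    coronal T2-weighted MR volumes of polycystic kidney disease patients.
    Implements a two-channel (image + kidney mask) 2-D encoder-decoder
    convolutional network trained with a soft Dice loss under k-fold
    cross-validation and fused by per-voxel majority vote, together with
    total-kidney-volume-stratified data splitting, NIfTI input/output, a
    synthetic MR phantom generator with ground-truth masks, and a full
    agreement-evaluation suite (Dice, Jaccard, sensitivity, precision,
    Hausdorff distance, total cyst volume, cystic index, linear
    regression and Bland-Altman analysis).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
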