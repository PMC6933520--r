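Package: gliowmh
Title: Joint 3D Segmentation of Glioma Sub-Regions and White Matter
    Hyperintensities on Multi-Parametric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for multi-class volumetric segmentation of brain MRI in
    which two disease processes coexist: glioma sub-regions (necrotic core,
    enhancing tumor, peritumoral edema) and white matter hyperintensities
    (WMH) from small vessel ischemic disease. Provides BraTS-style NIfTI
    case handling with label encoding and padding, a seeded synthetic
    multi-parametric MRI phantom generator with ground truth, lesion-biased
    patch sampling with flip/affine augmentation, a compiled 3D U-Net
    (encoder-decoder with skip connections, batch normalization, Adam
    training, cross-validation and ensembling) supporting 4-class and
    5-class outputs, and the evaluation stack used in this setting: Dice,
    95th-percentile Hausdorff distance over composite tumor regions,
    volume correlation and Bland-Altman agreement, WMH prevalence counts,
    volume-stratified median Dice, and paired model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
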