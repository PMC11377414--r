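Package: cunet
Title: Connected Dual U-Net for CT Lung Tumor Segmentation with
    Pseudo-PET Guidance
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a multitask connected (dual) U-Net for lung tumor
    segmentation from CT slices: a first U-Net synthesizes a pseudo-PET
    image from CT and a second U-Net segments the tumor, guided by
    cross-network skip connections from the first U-Net's decoder.
    Training follows a mean-teacher semi-supervised scheme that combines
    PET-paired studies without masks and mask-labeled studies without PET,
    with an EMA teacher, a ramped consistency weight, and focal plus dice
    segmentation losses. A clustering-based tumor-area detector refines
    predictions by extracting farthest-pixel-pair quadruples over a
    21-slice window, 2-means clustering, and rectangular region masking
    before re-prediction. Includes a synthetic thorax phantom generator,
    NIfTI I/O, preprocessing (1 mm resampling, center crop), and DSC, IoU
    and HD95 evaluation metrics. All network computation is implemented
    natively (RcppArmadillo), with no external deep-learning runtime.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    RNifti,
    jsonlite,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Segmentation, ImageImport, Software
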