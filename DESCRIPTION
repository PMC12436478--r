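Package: echostrain
Title: Left-Atrial Strain Extraction and Subclinical-AF Prediction from
    Echocardiographic Image Sequences
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end framework for predicting atrial high-rate
    episodes (AHREs, subclinical atrial fibrillation) from apical
    four-chamber echocardiography. Provides synthetic ultrasound phantom
    and patient-cohort generators with analytically known left-atrial
    strain, multi-class encoder-decoder segmentation of the LA cavity and
    wall trained with a soft-Dice plus cross-entropy loss, contour-length
    based LA strain extraction with 30-point equidistant resampling, a
    transformer classifier of AHRE duration fusing strain curves with ten
    clinical features under class-imbalance-weighted binary cross-entropy,
    image quality-control filters for clean segmentation subsets, and
    evaluation statistics (Dice, Bland-Altman agreement, ROC/AUC with
    Youden's J operating point, stratified k-fold cross-validation,
    independent t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    pROC
Config/testthat/edition: 3
biocViews: Software, Segmentation, Classification, Cardiology
RoxygenNote: 7.3.3
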