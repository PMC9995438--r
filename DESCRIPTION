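Package: ctpseg
Title: Voxel-Wise Machine Learning Segmentation of Ischemic Core and
    Penumbra from CT Perfusion Parameter Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the ischemic core and penumbra of acute
    stroke lesions from co-registered CT perfusion (CTP) parameter maps
    (delay time, cerebral blood flow, mean transit time and cerebral blood
    volume). Ground-truth lesion maps are derived by dual perfusion
    thresholds (delay time >= 3 s for the perfusion lesion, relative
    cerebral blood flow < 30% for the core) followed by single-lesion
    cleanup; class-balanced voxel sampling with 3x3x3 neighborhood patch
    extraction builds training matrices for multinomial logistic
    regression, random forest, gradient-boosted tree and support vector
    machine classifiers; fitted models are applied voxel-wise to whole
    studies and evaluated with Dice and Jaccard overlap statistics, volume
    agreement and cohort-level tests. A synthetic brain phantom generator
    with known lesion geometry and optional skull-rim artifacts supports
    development and validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    xgboost,
    ranger,
    glmnet,
    e1071,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
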