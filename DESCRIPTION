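Package: usradiomics
Title: BI-RADS Radiomic Features and Machine-Learning Classification for
    Breast Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies the BI-RADS lexicon descriptors of solid breast
    lesions on B-mode ultrasound images as ten computable radiomic
    features (equivalent-ellipse shape irregularity, orientation, margin
    sharpness, convex-hull spiculation measures, echogenicity, texture
    entropy, posterior shadowing, size), given a manual lesion
    delineation.  Provides a synthetic lesion-phantom generator with
    known ground truth, five benign/malignant classifiers (decision tree,
    random forest, multilayer perceptron, linear discriminant analysis,
    support vector machine) evaluated by stratified 10-fold
    cross-validation, greedy forward feature selection driven by
    cross-validated AUC, and ROC analysis with DeLong confidence
    intervals and Youden-index operating points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    MASS,
    nnet,
    png,
    pROC,
    randomForest,
    rpart,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
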