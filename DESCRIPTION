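Package: voxcnn
Title: Volumetric 3D CNN Screening of Cerebral Small Vessel Disease MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end computer-aided screening pipeline for grade-1
    cerebral small vessel disease from brain MRI. Converts per-patient
    DICOM slice series (mixed T1W/T2W/FLAIR sequences, mixed matrix
    sizes) into fixed-shape normalized 3D stacks, classifies them with a
    compact four-block 3D convolutional neural network (He
    initialization, ELU activations, batch normalization, L2
    regularization), trains with class-balancing augmentation and
    stratified k-fold cross-validation, reports confusion-matrix and ROC
    metrics, and localizes the evidence with volumetric Grad-CAM
    overlays. Ships a seeded synthetic MRI-phantom cohort generator that
    writes standard DICOM series with injected periventricular
    hyperintense lesions, so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
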