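Package: robustrad
Title: Robust Radiomic Analysis of DCE- and DW-MRI Parametric Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for classifying lesions from quantitative
    MRI: voxel-wise pharmacokinetic mapping of dynamic contrast-enhanced
    series (six model-free descriptors plus extended Tofts Ktrans, Ve, Vp),
    intravoxel incoherent motion (IVIM) fitting of multi-b-value diffusion
    series (D, D*, f), IBSI-style radiomic feature extraction (first-order,
    GLCM, GLRLM, GLSZM, NGTDM, GLDM; 93 features per map), screening of
    feature robustness to region-of-interest perturbation via the
    intraclass correlation coefficient, and selection-bias-free nested
    cross-validated classification with four feature selectors (AUC,
    ReliefF, LASSO, backward elimination) and four classifiers (LDA, k-NN,
    SVM, neural network).  Includes a synthetic phantom cohort generator
    with known kinetic and diffusion ground truth so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    minpack.lm,
    glmnet,
    MASS,
    class,
    e1071,
    nnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
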