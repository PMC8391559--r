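Package: dscradiomics
Title: Multicenter DSC-MRI Radiomics for IDH Mutation-Status Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible radiomics pipeline for dynamic
    susceptibility contrast (DSC) perfusion MRI of gliomas. The package
    simulates multi-center DSC cohorts with known class structure, selects
    characteristic perfusion time points (T0, Tmax, T2) from the tumor mean
    signal curve, standardizes images either conventionally (z-score, scale,
    shift) or dynamically via the transverse relaxation-rate transform
    deltaR2 = (1/TE) * log(baseline/signal), extracts an IBSI-aligned
    catalogue of 2499 three-dimensional radiomics features per patient
    (first-order, shape, GLCM, GLRLM, GLSZM, GLDM, NGTDM; original image and
    eight undecimated Coiflet-1 wavelet sub-bands at three time points),
    runs an imbalance-aware combinatorial model search ranked by Cohen's
    kappa under repeated stratified cross-validation with strict train-only
    fitting, validates the selected pipeline on held-out centers, and
    explains predictions via permutation importance and exact Shapley values
    for linear models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    Matrix,
    glmnet,
    ranger,
    e1071,
    rpart,
    class,
    xgboost,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
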