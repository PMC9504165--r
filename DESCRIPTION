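Package: dynradiomics
Title: Whole-Brain Dynamic Radiomics of 4D Perfusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study whole-brain dynamic radiomics features (DRF) of
    dynamic susceptibility contrast perfusion-weighted imaging (DSC-PWI) for
    ischemic stroke endpoints. Provides a seeded synthetic 4D perfusion cohort
    generator (gamma-variate bolus, spatially coherent texture, optional
    lesions with attenuated and delayed signal drop), temporal preprocessing
    (triple moving-average smoothing, reference volume), per-timepoint
    radiomics over an 18-image-type filter bank (original, Laplacian of
    Gaussian, wavelet sub-bands, intensity remaps) and six feature families
    (first order, GLCM, GLRLM, GLSZM, GLDM, NGTDM), significance filtering
    (Levene + t-test), Lasso and five dimensionality-reduction selectors
    (PCA, ICA, t-SNE, UMAP, Isomap), the four-group feature-combination
    strategy, and a ten-classifier ten-fold cross-validated AUC benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    RNifti,
    glmnet,
    e1071,
    rpart,
    nnet,
    randomForest,
    class,
    MASS,
    xgboost,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
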