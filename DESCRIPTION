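Package: mmcnet
Title: Individual Multi-Modal Brain Connectivity Networks from Structural
    and Metabolic Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs individual brain connectivity networks from paired
    structural (gray-matter volume) and metabolic (FDG-PET uptake) regional
    voxel data. Per-region principal components are learned on stratified
    bootstrap resamples of an auxiliary AD/NC cohort and used to project
    target-domain subjects into replicate-by-region feature matrices;
    region-wise multi-task l2,1-penalized sparse regressions across
    modalities yield per-PC support patterns that are encoded into edge
    weights by binary-to-decimal conversion. Includes a synthetic cohort
    generator with planted group effects and cross-regional latent
    couplings, SVM-RFE feature selection with nested cross-validated
    hyperparameter search under leave-one-out cross-validation, edge-wise
    two-sample testing with false-discovery-rate control, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    pROC,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
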