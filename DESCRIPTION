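Package: m3class
Title: Multimodal Multilevel Multiclassifier Discrimination for Resting-State Neuroimaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminative analysis of two-group neuroimaging cohorts with the
    M3 (multimodal imaging, multilevel characterization, multiclassifier)
    scheme: voxelwise resting-state metrics (ALFF, ReHo, degree centrality,
    voxel-mirrored homotopic connectivity) with nuisance regression and
    optional global signal regression, atlas ROI-mean feature extraction,
    maximum-uncertainty linear discriminant analysis base classifiers fused
    by weighted voting, t-test feature selection with a P-threshold grid
    searched under leave-one-out cross-validation, fold-aggregated feature
    weights, and significance machinery (label-permutation tests, ROC AUC,
    DeLong comparison of correlated AUCs). Includes a synthetic-data
    generator producing feature tables with planted group effects, small 4D
    images with known spectral content, and demographics tables, so the
    whole pipeline is exercisable end to end without real data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
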