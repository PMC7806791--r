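Package: growthmorph
Title: Longitudinal Tensor-Based Morphometry of Early Brain Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A desk-scale longitudinal tensor-based morphometry (TBM)
    pipeline for multi-visit, two-channel (T1/T2-like) anatomical volumes:
    decile-landmark intensity normalization, iterative unbiased
    age-specific template construction, multi-resolution dual-channel
    cross-correlation diffeomorphic registration, displacement-field
    calculus (composition, inversion, log-Jacobian determinant maps in a
    common 12-month reference space), voxel-wise linear mixed-effects
    growth-trajectory modelling with forward model selection, pooled
    Benjamini-Hochberg false discovery rate thresholding of statistical
    maps, and connected-cluster reporting with optional atlas labels.  A
    synthetic-data module generates phantom imaging cohorts and
    log-Jacobian datasets with the longitudinal covariance structure the
    analysis assumes, so every stage is testable without access to a real
    cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    lmerTest,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
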