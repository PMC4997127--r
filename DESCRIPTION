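Package: pldacv
Title: Sparse Penalized Discriminant Reduction and Nested Cross-Validation
    for Brain Volume Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-class penalized linear discriminant analysis (pLDA) with a
    lasso penalty and a diagonal within-class scatter estimate, solved by
    minorization-maximization, together with stability selection over random
    half-samples for whole-brain voxel-wise feature selection. Includes the
    standard comparison reductions (mass-univariate t-test selection with
    optional false-discovery-rate correction, principal component extraction),
    linear discriminant and linear support-vector classifiers suited to
    p >> n data, and leave-one-out cross-validation in two designs: reduction
    fit once on all subjects (the biased design) and reduction nested inside
    every fold (the correct design), with accuracy/sensitivity/specificity,
    McNemar and one-sample binomial comparisons. A synthetic cohort generator
    produces two-class masked 3-D volumes with spatially smooth heterogeneous
    noise and planted discriminative clusters, so the optimistic bias of
    non-nested feature selection can be demonstrated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    ggplot2,
    jsonlite,
    rlang,
    RNifti,
    stats,
    tibble,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
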