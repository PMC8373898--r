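Package: anxdecode
Title: Multivoxel Pattern Analysis of Block-Design Task fMRI with Region
    Super Learning and Shared-Response Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decodes clinical group membership and stimulus condition from
    block-design task fMRI. Provides NIfTI/BIDS-style readers that turn 4D
    BOLD volumes, a parcellation atlas and event tables into per-subject
    time-point-by-voxel datasets; a synthetic block-design cohort generator
    with planted group and shared-stimulus signals; a nested cross-validated
    super learner that treats atlas regions as a hyperparameter of a boosted
    logistic classifier with per-subject majority voting; a shared response
    model (deterministic alternating-Procrustes and probabilistic EM) for
    functional alignment; cross-subject stimulus decoding with a linear SVM;
    condition-beta estimation with a grouped Mann-Whitney comparison and
    representational similarity matrices; a region-correlation connectome with
    seed-edge extraction; and a coupled four-class group-by-stimulus ensemble.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    glmnet,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
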