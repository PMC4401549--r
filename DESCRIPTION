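Package: scnpdx
Title: Single-Cell Network Profiling Classifiers for AML Induction Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating single-cell network profiling
    (SCNP) response classifiers from multi-well phospho-flow cytometry data in
    acute myeloid leukemia. Includes a synthetic cohort and event-level
    simulator, rainbow-bead ERF calibration, hierarchical gating (intact /
    viable / blast / cPARP-negative blast), per-node signaling metrics (Basal,
    log2 fold change, scaled Mann-Whitney Uu and Ua, percent healthy), the
    locked two-node apoptosis classifier for predicting complete response to
    cytarabine-based induction therapy, a classifier-development pipeline
    (node prescreening, combination logistic models, LASSO, bootstrap optimism
    adjustment, out-of-bag AUROC), a validation-statistics suite (exact
    Mann-Whitney AUROC test, BCa and DeLong confidence intervals, power
    simulation, paired-tissue concordance, subgroup analysis), and
    Pocock-Simon minimization randomization for cohort allocation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
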