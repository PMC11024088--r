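Package: bbbfp
Title: Blood-Brain-Barrier Permeability Modelling with Entropy-Selected
    Property Fingerprints
Version: 0.1.0
Authors@R:
    person("bbbfp", "developers", email = "bbbfp@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building blood-brain-barrier (BBB) permeability
    classifiers from molecular descriptor tables. Implements differential
    Shannon-entropy (MI-DSE) feature scoring with Pearson-correlation
    redundancy pruning, structural-key extraction from class-dependent
    missing-value patterns, thermometer-coded property-based bit
    fingerprints, modified Kennard-Stone train/test splitting under
    Euclidean, Mahalanobis or 1-Tanimoto distances, random-forest and
    support-vector classifiers with exhaustive grid search and stratified
    10-fold cross-validation, a full confusion-matrix metric suite
    (including MCC, Cohen's kappa and ROC-AUC), and a Mahalanobis
    applicability-domain distance for new predictions. A seeded synthetic
    descriptor-table generator makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.9) with scikit-learn and rdkit on PATH
    (used through subprocess adapters for learner fitting and structure
    handling)
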