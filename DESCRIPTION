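Package: ensdock
Title: Ensemble Docking Analysis for Receptor Conformation Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing ensemble-docking virtual screens against
    pools of receptor conformations. Provides a failure-aware docking score
    matrix container with CSV input/output, rank-based ROC AUC enrichment
    statistics with explicit censoring of failed dockings, best-score
    aggregation across ensemble members, exhaustive selection of the
    best-performing size-k conformation ensembles under single and summed
    AUC objectives, affinity-propagation clustering of trajectory frames on
    binding-site heavy-atom RMSD with exemplar extraction, hierarchical
    binding-site clustering of crystal structures, grid-based pocket volume
    estimation, and seeded synthetic generators for score matrices and toy
    coordinate sets with planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
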