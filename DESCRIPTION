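Package: sarscape
Title: Structure-Activity Relationship Landscape Analysis for Kinase
    Inhibitor Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for structure-activity
    relationship (SAR) landscape analysis of compound potency datasets
    such as kinase inhibitor series: curation of SMILES/IC50 records
    (desalting, unit conversion, duplicate resolution, activity
    labeling), circular (Morgan) fingerprints and Tanimoto similarity,
    Ward hierarchical clustering with silhouette-guided cluster-count
    scans and per-cluster maximum common substructure scaffolds,
    similarity-thresholded chemical space networks, activity-cliff
    enumeration with safe-bet/dead-end compound profiling,
    hypergeometric structural-alert detection over circular atom
    environments, and interpretable IF-THEN rule extraction from
    depth-limited decision trees on a molecular descriptor panel. A
    synthetic dataset generator with planted ground truth (scaffold
    families, cliffs, enriched fragments, descriptor rules) makes every
    stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    cluster,
    igraph,
    jsonlite,
    methods,
    rpart,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
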