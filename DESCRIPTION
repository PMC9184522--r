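Package: CCCbench
Title: Consensus Ligand-Receptor Scoring and Evaluation of Cell-Cell
    Communication
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers cell-cell communication from cluster-annotated
    single-cell expression data by computing six ligand-receptor scoring
    systems (CellPhoneDB-style permutation means, Connectome-style
    z-score weights, NATMI-style specificity edges, SingleCellSignalR
    regularised scores, one-vs-rest logFC means, and CytoTalk-inspired
    crosstalk scores) under one interface, aggregating them into a
    robust-rank-aggregation consensus, and evaluating predictions by
    top-k overlap, robustness to noise in data and prior knowledge, and
    agreement with auxiliary modalities (cytokine activity footprints,
    spatial colocalization, receptor protein abundance). Also provides a
    comparison toolkit for ligand-receptor prior-knowledge resources
    (overlap, similarity, category enrichment, localisation filtering)
    and a seeded synthetic-data generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, CellInteraction, Software
RoxygenNote: 7.3.3
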