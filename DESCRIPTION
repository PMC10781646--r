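Package: cytodict
Title: Cytokine Response Dictionaries and Response Enrichment for
    Single-Cell Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds per-cell-type cytokine response references from
    perturbational single-cell RNA-seq compendia and scores new expression
    data against them. Provides quality control and library-size
    normalization, Wilcoxon rank-sum differential expression with
    replicate-consistency filtering, response-magnitude maps, non-negative
    matrix factorization gene programmes, hypergeometric calling of
    cytokine-driven polarization states, cytokine production and receptor
    expression maps with ligand-response and ligand-receptor interactomes,
    cosine-projection enrichment of user transcriptomes for cytokine
    activity and polarization, and a negative-binomial synthetic compendium
    generator with planted ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, DifferentialExpression,
    GeneExpression, Network
RoxygenNote: 7.3.3
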