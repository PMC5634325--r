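Package: clustviz
Title: Clustered-Heatmap Visualization Engine for Labeled Omics Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Back-end engine that turns a labeled, categorized data matrix
    (genes, post-translational modifications, or single cells by samples or
    markers) into a fully specified visualization JSON document: hierarchical
    clustering with cosine distance and average linkage, multi-level
    dendrogram slice groups, rank orders, pre-computed row-filtered views,
    row and column similarity matrices, K-means downsampling with category
    propagation for mass-cytometry-scale data, and exact binomial-proportion
    category enrichment of dendrogram clusters. Includes seeded synthetic
    generators emulating PTM/expression, CyTOF-like single-cell, and
    CCLE-like expression inputs, plus the three corresponding preprocessing
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    limma,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
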