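Package: crossConcord
Title: Cross-Species Transcriptome Concordance via SAM, Consensus
    Clustering and Ortholog Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for cross-species comparative
    transcriptomics of bulk expression microarray studies. Implements
    Significance Analysis of Microarrays (SAM) with permutation-based
    false discovery rate control and fold-change gating, unsupervised
    hierarchical clustering with 1-Pearson distance and average linkage,
    a consensus cluster-number estimator over three quality indices
    (Silhouette, homogeneity-separation, weighted inter/intra ratio),
    many-to-many probe-to-ortholog expression collapsing with
    average-and-split rules, mouse-to-human fold-change concordance
    scoring, delta-delta-Ct qPCR validation, and seeded synthetic
    dual-species study generators so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    limma,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'clustering.R'
    'concordance.R'
    'crossConcord-package.R'
    'io-tables.R'
    'ortholog.R'
    'sam.R'
    'pipeline.R'
    'preprocess.R'
    'qpcr.R'
    'simulate.R'
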