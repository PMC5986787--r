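Package: rootapex
Title: Developmental-Stage Transcriptomics of Root Apical Meristem Exhaustion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for de novo transcriptomes of determinate-growth
    root apices sampled across developmental stages. Provides RPKM
    quantification with reference-gene stability ranking, exact
    negative-binomial tests for differential expression with a common
    quantile-adjusted conditional-likelihood dispersion and the
    fold-change/FDR/expression-floor filter cascade, sample-level principal
    component analysis including cross-species co-projection on orthologous
    transcripts, k-means clustering of expression profiles, hypergeometric
    gene-ontology enrichment, Smith-Waterman based best-bidirectional-hit
    orthologue calling with coverage, E-value and protein-domain gates,
    projection of a curated transcriptional regulatory map onto a target
    transcriptome, six-frame open-reading-frame classification of candidate
    lineage-specific transcripts, and a seeded synthetic-data generator that
    reproduces the statistical and sequence structure the pipeline assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
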