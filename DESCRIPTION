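Package: hegatlas
Title: Homing Endonuclease Gene Atlas for Phage Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics pipeline for mapping HNH homing endonuclease
    genes (HEGs) across cohorts of annotated phage genomes. Builds protein
    ortholog families by Markov clustering of an all-vs-all similarity graph,
    derives a consensus single-copy core-gene scaffold with functional-module
    labels, classifies HNH endonucleases against packaged reference families
    (I-HmuI-like, PacI-like, GVE2-like, truncated), anchors each HEG to its
    flanking core genes and consolidates insertion loci cohort-wide, builds
    per-family neighbour-joining phylogenies with bootstrap support and tests
    cluster-metadata association, and computes phage titres and efficiency of
    plaquing from plaque-assay counts. Ships a synthetic phage-cohort
    generator with full ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    ape,
    phangorn,
    igraph,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
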