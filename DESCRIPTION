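Package: phylocomp
Title: Phylogenetic Analysis of Cancer Driver States and Compensatory
    Mutation Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cancer-driver amino-acid states in deep gene-family
    phylogenies and infers within-gene compensatory mutation ensembles.
    Implements column homogeneity scores, tree-based leaf weighting,
    weighted-Fitch ancestral state reconstruction with branch-midpoint
    transitions, a binomial test for driver/compensator co-occurrence on
    the tree, Poisson-tail association scores for mutation pairs in tumor
    tables and leaf-weighted alignments, clade-level driver prevalence
    statistics, and coverage scoring of protein-structure hits. A seeded
    synthetic-data generator produces trees, alignments with planted
    driver and compensator events, taxon annotations, and tumor tables so
    the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
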