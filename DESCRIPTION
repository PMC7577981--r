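Package: clonalevo
Title: Clonal Evolution Analysis of Single-Cell DNA Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs tumor clonal evolution from single-cell DNA
    sequencing genotypes. Provides per-cell genotype calling with
    depth- and VAF-based filtering, allele-dropout (ADO) estimation from
    germline heterozygous SNPs, Bayesian mutation-tree inference by
    Markov-chain Monte Carlo under a false-positive/false-negative error
    model (with locus-specific dropout learning, zygosity-constrained
    search for loss-of-heterozygosity ordering, longitudinal cell
    attachment, and credible intervals on subclone sizes), clonal
    composition and Shannon diversity, linear/branching/convergent
    evolution-pattern classification, and mutation co-occurrence
    statistics at the cell, patient, and clone level. Includes a
    synthetic-data generator emulating targeted single-cell panels so the
    whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
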