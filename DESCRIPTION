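Package: genedecay
Title: Pseudogene Detection and Relaxed-Selection Analysis for
    Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring gene loss from coding sequences on a
    species phylogeny: scanning of open-reading-frame disruptions
    (frameshifting indels, premature stop codons) against a functional
    reference, Dollo mapping of inactivating mutations onto the tree,
    Goldman-Yang codon substitution models (branch, site, and clade
    models) fitted by maximum likelihood with likelihood ratio tests for
    relaxation and divergence of selective pressure, protein-level
    conservation and physicochemical-property analyses, and a
    seed-deterministic codon sequence simulator with pseudogenizing
    mutation injection for validation against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    seqinr,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
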