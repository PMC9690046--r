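Package: mitovar
Title: Mitochondrial Control-Region Variant Calling and Case-Control
    Association from Mitogenome Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns complete or partial human mitogenome sequences against an
    rCRS-coordinate reference, extracts and normalizes variants with
    HGVS-style 3'-shifting in homopolymer tracts, types the D310 poly-C
    locus, screens phantom (systematic artifact) polymorphisms with a
    score-and-recurrence rule, and computes coverage-aware carrier-frequency
    2x2 tables with Pearson chi-square association tests for case-control
    cohorts. Includes a synthetic-cohort simulator with a known implanted
    truth table so every stage of the pipeline is testable without external
    sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
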