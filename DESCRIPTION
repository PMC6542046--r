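Package: httguard
Title: Read-Based Discrimination of Contamination and Horizontal
    Transposon Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to decide whether a transposable element shared between
    a parasite and its host genome reflects horizontal transposon transfer
    or sequencing-library contamination. Retroelement-bearing long reads or
    read pairs are selected, repeat-masked, and their non-repetitive
    remainder is classified against "self" and "non-self" genome databases;
    dataset-level fractions yield a contamination/endogeny call. The package
    also provides reciprocal best-hit screening of retroelement libraries
    against genome sets, per-species consensus reconstruction, consensus
    identity matrices, copy defragmentation, neighbor-joining trees, and
    CpG-excluded Kimura 2-parameter repeat landscapes, together with a
    seeded simulator of HTT, contamination and negative scenarios used
    throughout the test suite.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
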