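Package: mztdecay
Title: Maternal mRNA Decay Dynamics and Small-RNA Regulation During the
    Maternal-to-Zygotic Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies maternal transcript decay dynamics across the
    MII-oocyte, 2-cell and 4-cell stages of mouse pre-implantation
    development, assigns AGO2-knockdown and zygotic-genome-activation
    dependence by log2-margin overlap rules, maps endogenous siRNAs and
    microRNAs onto maternal mRNAs with a mismatch-bounded antisense
    matcher with multimap suppression, screens long noncoding RNAs for
    long complementary blocks against targeted mRNAs, scans 1-kb
    TSS-upstream promoter windows for candidate small activating RNAs,
    and estimates first-order decay kinetics and qPCR fold changes.
    Ships a synthetic-data generator with recorded ground truth so the
    whole pipeline is exercisable and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
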