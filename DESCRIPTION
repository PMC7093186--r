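Package: nmrclock
Title: Targeted Bisulfite Methylation Age Clock for the Naked Mole-Rat
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to build and evaluate a DNA-methylation age clock for
    the naked mole-rat (Heterocephalus glaber) from targeted bisulfite
    amplicon sequencing.  Simulates age-structured amplicon panels and
    bisulfite-converted reads, quantifies per-CpG methylation with
    coverage filtering, screens CpGs for association with age (aDMPs),
    fits an elastic-net age predictor by cyclic coordinate descent with
    leave-one-out cross-validation, and compares epigenetic ageing rates
    between tissues.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
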