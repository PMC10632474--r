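Package: tradistat
Title: Essentiality Analysis for Saturated Transposon Insertion Libraries
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Downstream analysis of transposon-directed insertion site
    sequencing (TraDIS) libraries. Computes per-gene insertion indices,
    fits a two-component exponential/gamma model to the bimodal index
    distribution and classifies genes as essential, non-essential or
    unclear by a log2 likelihood-ratio rule; detects domain-essential
    genes with an insertion-free sliding window; derives orthologs by
    bidirectional best hit from BLAST tabular output and compares
    essentiality across species; profiles taxonomic conservation;
    clusters paralogous proteins via second-order similarity neighbours;
    and builds phyletic presence/absence matrices with hierarchical
    clustering. Includes a synthetic-library simulator with known ground
    truth for validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    fitdistrplus,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
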