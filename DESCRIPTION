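Package: hmcblocks
Title: Consensus 5hmC Blocks and Developmental Hydroxymethylome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 5-hydroxymethylcytosine (5hmC) enrichment
    sequencing across sample cohorts. Builds consensus "5hmC blocks" from
    per-sample peak calls, quantifies their enrichment in genomic features
    against a random-placement null, derives cohort-specific (developmental)
    blocks, links blocks to gene-expression levels and developmental
    expression groups, performs GREAT-style regulatory-domain binomial and
    hypergeometric term-enrichment tests, computes single-base 5mC/5hmC
    levels from TAB-Seq counts, and simulates complete toy studies with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
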