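Package: comutcnv
Title: Co-Occurrence and Allelic Imbalance of Somatic Mutations and Copy-Number Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for mutation-copy-number epistasis in tumor
    cohorts. Provides a degree-preserving permutation test for positively
    selected co-occurrence of somatic mutations and gene-level copy-number
    events with Edgington combination across centers, regression screens of
    copy-number dosage effects on variant allele fraction, the Binoculars
    matched-background exact binomial test for per-mutation allelic imbalance
    at DNA and RNA level, a mutation-by-copy-number expression interaction
    model, full-gene eccDNA containment counting, and a seeded synthetic
    cohort generator that emulates multi-center tumor genomics inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    stats,
    utils,
    readr,
    stringr,
    ggplot2,
    generics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
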