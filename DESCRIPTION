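Package: evanno
Title: Extended Annotation, Scoring and Reporting of Coding Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes single nucleotide variants called from whole
    exome sequencing. Maps variants onto gene models, selects coding
    variants, builds pseudo-germline sets by intersecting samples, exports
    pileup files for the Variant Effect Predictor (VEP), joins VEP output
    with local evidence tables (literature counts, COSMIC burden, disease
    associations, functional terms, cancer census membership, tissue
    expression), computes a composite per-variant relevance score, and
    emits filtered ranked reports and mean-normalized expression
    summaries. Ships a deterministic synthetic-data generator so the whole
    workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
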