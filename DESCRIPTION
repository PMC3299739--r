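Package: chipdyn
Title: Window-Based ChIP-Seq Enrichment Calling and Differential
    Histone-Mark Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of histone-modification ChIP-seq between two
    biological conditions. Reads are deduplicated, extended, and counted on a
    fixed-width window grid; per-condition enriched windows are called against a
    matched input library under a Poisson model with an empirical
    input-versus-input false discovery rate; differential regions between the
    two conditions are detected by a two-stage procedure (background and bias
    filtering, then two-sample quantile normalization and a fold-change
    threshold); per-gene mark states, bivalency transitions, expression-quintile
    cross-tabulations and TSS-relative histograms integrate the calls with a
    gene expression table. A synthetic-read generator with a planted truth
    table supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
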