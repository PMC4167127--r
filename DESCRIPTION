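Package: motifzoom
Title: Local and Differential Local Motif Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds sub-regions of equal-length DNA or RNA sequences where the
    best matches of known motifs (position weight matrices) are concentrated,
    using a binomial test over candidate sub-regions with a conservative
    multiple-testing adjustment and E-values, and tests whether that local
    enrichment differs between a primary and a control sequence set with a
    two-sided Fisher exact test (differential local motif enrichment analysis).
    Includes MEME-format motif input/output, best-match PWM scanning with
    optional per-motif score-threshold optimization, greedy selection of
    non-overlapping enriched sub-regions, a control-suitability protocol for
    paired ChIP-seq experiments, genomic region preparation (peak-centered
    windows, TSS proximity splits, sequence extraction), a synthetic-data
    generator with planted motif sites, and tidy reporting with site
    probability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
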