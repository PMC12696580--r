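Package: tepair
Title: Transposable Elements and Homolog Pairing from Haplotype-Resolved Hi-C
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links transposable-element (TE) content to the degree of
    homolog pairing measured by haplotype-resolved Hi-C. Computes
    per-window pairing scores (log2 average trans-homolog contact
    frequency) from sparse or dense contact matrices, aggregates TE
    annotations, SNP calls and read coverage into the same fixed-size
    genome windows, and applies the statistical battery used in
    TE/pairing studies: TE versus no-TE group comparisons, per-family
    t or Wilcoxon tests with Bonferroni correction, exact binomial
    bias tests of family pairing against the genome-wide reference,
    trend tests against read depth, and genotype-class comparisons.
    Includes a fully specified synthetic diploid data generator with
    known ground-truth pairing effects so the whole pipeline is
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
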