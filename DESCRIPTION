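Package: smoothsv
Title: Structural Variant Consensus, ecDNA Detection and CNV Profiling for
    Single-Cell Long-Read Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of sparse single-cell long-read (HiFi/CCS)
    whole-genome sequencing. Detects extrachromosomal circular DNA (ecDNA)
    from chiastic two-segment split-read alignments with tandem-repeat and
    duplication filtering; builds multi-cell consensus structural-variant
    call sets with type-aware breakpoint clustering and benchmarks them
    (precision, recall, FPR, FNR, harmonic mean, F1); profiles copy number
    in fixed genomic windows with ploidy normalization, coefficient-of-
    variation noise estimates and circular binary segmentation; and
    benchmarks single-nucleotide variant calls by multi-cell support.
    Includes a synthetic single-cell long-read simulator (one-adaptor Tn5
    fragmentation, planted SVs, circles and copy-number steps) so every
    stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stringr,
    readr,
    jsonlite,
    igraph,
    stats,
    utils,
    tools,
    Rsamtools,
    GenomicAlignments,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
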