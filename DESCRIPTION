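Package: mcseq
Title: Whole-Genome Bisulfite Sequencing Methylome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for MethylC-seq (whole-genome
    bisulfite sequencing) analysis at single-base resolution: cytosine
    context annotation on both strands, bisulfite read pre-processing and
    toy-scale three-letter alignment, binomial methylcytosine calling with
    false-discovery-rate control calibrated on an unmethylated
    mitochondrial contig, CpG island detection and methylation
    classification, sliding-window identification of differentially
    methylated regions between two sample groups, and integration of
    promoter/gene-body methylation with gene expression. Includes a full
    synthetic-data generator (genomes, methylomes with planted
    differentially methylated regions, bisulfite reads, per-cytosine count
    tables, coupled expression values) so every stage of the pipeline can
    be exercised against known truth.
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
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
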