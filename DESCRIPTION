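Package: diagseq
Title: Diagnostic DNA-Seq Analysis: Read QC, Seed-and-Extend Alignment,
    Variant Calling, Annotation and Reporting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained DNA sequencing workflow for small diagnostic
    laboratories: quality control, filtering and demultiplexing of raw
    reads; a hash-index seed-and-extend read aligner with Gotoh affine-gap
    dynamic programming and paired-end support; coverage reporting over
    regions of interest; a pileup-based SNP and small-indel caller in the
    Varscan 2 style with a one-tailed Fisher exact test and artifact
    filters; transcript-level consequence annotation with local
    known-variant, population-frequency and phenotype tables; diagnostic
    variant filtering, classification with cross-patient recurrence, and
    report generation; plus a deterministic synthetic-data generator that
    produces reference sequences, gene models, diploid sample genomes with
    a truth set, and reads with errors, adapters and barcodes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    Rcpp,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
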