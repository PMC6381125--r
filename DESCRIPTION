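Package: moRseq
Title: Quantification of miRNAs, isomiRs and miRNA-Offset RNAs from Small RNA-Seq
Version: 0.3.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis pipeline for the
    quantification of annotated mature miRNAs, the characterization of their
    sequence variants (isomiRs), the structure-guided discovery of sister
    miRNAs on single-mature hairpins, and the detection of miRNA-offset RNAs
    (moRNAs) flanking the mature species on the precursor hairpin. Includes a
    fully seeded synthetic-data generator (reference hairpins, genome and
    per-sample FASTQ with planted expression truth), adapter/quality/abundance
    read filtering, seed-and-verify ungapped short-read mapping with a
    multimapping noise filter, a nearest-neighbour stacking-energy model for
    hairpin folding and small RNA:target heteroduplexes, median-of-ratios
    normalization with negative-binomial exact tests and Benjamini-Hochberg
    correction for subgroup differential expression, and a constrained
    seed-and-energy moRNA target-site scanner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
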