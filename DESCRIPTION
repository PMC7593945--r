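Package: trfquant
Title: Quantification and Differential Analysis of tRNA-Derived Fragments
    from Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Direct counting of annotated tRNA-derived fragments (tRF-1,
    tRF-3, tRF-5), intact tRNAs and mature miRNAs in small RNA-seq reads by
    exact or mismatch-tolerant sequence matching against a collapsed
    unique-sequence reference; length-based tRF subtype and tRNA-half
    classification with 5'-oligo-G motif detection; reads-per-million
    normalization, group-wise fold change and unpaired t statistics, codon
    level aggregation of tRNA abundance, and 2^-ddCt relative quantification;
    AGO-association filtering, CLASH target intersection with ECDF-shift
    (Kolmogorov-Smirnov) repression analysis, and reciprocal tRNA-tRF
    correlation; plus a seeded synthetic-data generator emitting references,
    ground truth and FASTQ libraries with negative-binomial group structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
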