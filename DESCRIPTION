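Package: motifbench
Title: Leakage-Resistant Benchmarking of Transcription Factor Binding Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of cross-platform benchmarks for
    transcription factor (TF) binding-specificity models. Builds
    leakage-resistant positive/negative datasets from ChIP-Seq and genomic
    HT-SELEX peaks, HT-SELEX and SMiLE-Seq reads, and protein-binding
    microarray (PBM) intensities; scores position frequency matrices with
    best-hit (log-odds) and sum-occupancy scanning; computes AUROC, AUPRC,
    top-fraction means, and Kendall tau-b against SELEX cycles; evaluates
    allele-specific binding predictions with exact PWM P-values and
    concordance curves; and aggregates results into hierarchical team
    rankings with stability subsampling. Includes a synthetic multi-platform
    data generator with planted motifs so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    data.table,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
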