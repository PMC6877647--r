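Package: m6Aribo
Title: CDS m6A Methylation, Ribosome Pausing and mRNA Structure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transcript-level analysis of N6-methyladenosine (m6A) in coding
    sequences and its consequences for translation. Implements a
    peak-over-median / peak-over-input (POM/POI) sliding-window m6A peak
    caller with replicate intersection and knockdown-sensitivity calls,
    RPKM-based translation efficiency with k-nearest-neighbour matched
    non-methylated controls, A-site metagene profiles and codon-level
    pausing scores from ribosome-profiling 5'-end counts, condition-contrast
    detection of ribosome pausing regions, sliding-window minimum free
    energy profiles with dinucleotide-preserving shuffle z-scores, icSHAPE-like
    reactivity aggregation with Gini indices, and cross-species m6A
    conservation through pairwise ortholog alignments. A seed-deterministic
    synthetic-data generator produces transcriptomes and per-nucleotide
    MeRIP, RNA-seq, Ribo-seq and reactivity tracks with planted ground truth
    so every stage of the pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    Biostrings,
    rtracklayer,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
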