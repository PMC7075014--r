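Package: atacdiff
Title: Differential Chromatin Accessibility from Low-Input ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for comparing chromatin accessibility
    between two conditions profiled by ATAC-seq, designed for the common
    setting where one condition is severely cell-number limited. Provides
    insertion-site pileup with shift/extension smoothing, Poisson
    local-background peak calling with Benjamini-Hochberg q-values, broad
    domain calling for repressive histone marks, depth-normalized binned
    log2-ratio tracks, a per-region log2-sum differential score with a
    fixed selection threshold, condition-exclusive region detection,
    genomic feature classification, window-based region-to-gene linking,
    co-location with differential-expression tables and chromatin-mark or
    transcription-factor occupancy, hypergeometric gene-set enrichment,
    and coverage matrices for heat maps. A fully deterministic synthetic
    data generator with planted ground truth supports validation of every
    stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
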