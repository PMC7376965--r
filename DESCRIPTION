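Package: cfpeakpanel
Title: Consensus Peaks and Epigenetic Marker Panels for Cell-Free DNA
    Methylation Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for enrichment-based cell-free DNA methylation
    (5mC) and hydroxymethylation (5hmC) profiling: fixed-width consensus peak
    construction with score-per-million normalization and iterative overlap
    removal, reproducibility-threshold selection by per-peak Fisher tests,
    FPKM quantification of fragments in peaks, differential peak calling,
    stability-selection elastic-net marker panels with weighted diagnosis
    scores, two-channel model integration, genomic annotation enrichment, and
    a synthetic cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
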