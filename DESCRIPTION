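Package: inflamethyl
Title: Multi-Cohort EWAS Machinery for DNA Methylation Signatures of
    Chronic Low-Grade Inflammation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for large multi-cohort epigenome-wide
    association studies of serum C-reactive protein (CRP): per-cohort
    regression of log CRP on CpG methylation with probe and outlier
    filters, inverse-variance-weighted meta-analysis with double genomic
    control, Fisher-z meta-analysis of inter-CpG correlations with
    distance profiling, 5 kb locus pruning and shared-nearest-neighbor
    density clustering, bidirectional two-sample Mendelian randomization
    with triangulation, Baron-Kenny mediation with the Aroian-Sobel test,
    permutation enrichment against genomic feature tracks with
    standard-error-matched null sets, and beta-weighted methylation risk
    scores with odds-ratio to relative-risk transformation. Includes a
    multi-cohort synthetic data generator with a known causal graph so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    metafor,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
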