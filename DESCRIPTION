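Package: txcascade
Title: Knowledge-Guided Temporal Clustering and Transcriptional Cascade
    Reconstruction for Time-Course Expression Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved transcriptomics of cellular
    stress responses. Implements per-timepoint differential expression with an
    empirical-Bayes moderated t-statistic, hierarchical clustering of temporal
    log2 fold-change profiles with selection of the number of clusters by
    transcription-factor target-set enrichment, per-cluster transcription
    factor enrichment and pathway over-representation, signature-overlap and
    directional gene-set statistics, rule-based reconstruction of a temporal
    transcriptional cascade, and a synthetic-data generator that plants a
    known cascade for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    e1071,
    igraph
Config/testthat/edition: 3
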