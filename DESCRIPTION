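Package: cernet
Title: Competing Endogenous RNA Network Inference from Multi-Class
    Transcriptome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers lncRNA/circRNA-miRNA-mRNA competing endogenous RNA
    (ceRNA) networks from multi-class RNA expression matrices and predicted
    miRNA-target tables, as used in two-condition follicle-selection
    transcriptome studies. Provides differential-expression calling with
    class-specific thresholds, Spearman anticorrelation filtering of
    miRNA-target edges, Pearson co-expression screening of candidate ceRNA
    pairs, a hypergeometric shared-miRNA-response-element test, triad and
    network assembly with degree-based hub ranking, cis/trans lncRNA target
    assignment from genomic intervals, generic hypergeometric
    over-representation analysis, and a synthetic-data generator with
    planted ground-truth structure for end-to-end validation.
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
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
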