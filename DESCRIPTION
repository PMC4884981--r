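Package: lncprofiler
Title: Multi-Cancer lncRNA Expression Profiling and Functional Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for profiling long noncoding RNAs (lncRNAs)
    across paired tumor/normal expression studies in multiple tissue types.
    Provides quantile normalization and clustering preprocessing, per-tissue
    differential expression with fold-change and FDR calling intersected into
    common up/down sets, genomic-context classification of lncRNAs relative to
    protein-coding genes with class-specific neighbor assignment,
    guilt-by-association functional inference via correlation-weighted gene-set
    enrichment, competing-endogenous-RNA (ceRNA) tri-color network construction
    and minimal motif discovery, and self-organizing-map based tissue-specificity
    calling.  A synthetic-data generator with planted ground truth drives
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
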