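Package: pausekit
Title: Promoter-Proximal Pausing Analysis from Nascent Transcription Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies RNA polymerase II promoter-proximal pausing from
    stranded nascent-transcription coverage (GRO-seq style): per-gene
    promoter and gene-body signal densities, the pausing release ratio
    (PRR), condition fold changes and classification of genes into
    paused/other/decreased groups, ECDF and two-sample Kolmogorov-Smirnov
    comparisons, TSS-anchored and peak-centered metaplot matrices,
    replicate and cross-assay consensus peak intersection with FDR
    filtering, genomic-feature annotation of peaks, and hypergeometric
    over-representation analysis of gene groups. Includes a synthetic-data
    generator with known pausing structure and a controllable
    pause-release effect so every stage is testable end to end, plus a
    config-driven pipeline orchestrator with provenance tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    fgsea,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
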