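Package: vmpscan
Title: Detection and Characterisation of Age-Related Variably Methylated
    Positions
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies CpG sites whose DNA methylation variance increases
    with age (aVMPs), independent of changes in mean methylation and of
    blood cell composition. Implements a two-stage heteroscedasticity scan
    on methylation beta values, classification of aVMPs into gain, loss and
    constant subtypes, per-sample methylome Shannon entropy, Z-scores
    against a young reference, clustering of aVMPs into variably methylated
    regions (aVMRs), hierarchical cis and trans mapping of aVMP methylation
    to gene expression (eQTM), odds-ratio enrichment against interval
    annotations such as chromatin-state segments, and replication of scan
    results across cohorts. A synthetic-cohort generator with planted
    ground truth makes every stage testable without access to restricted
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
biocViews: DNAMethylation, Epigenetics, DifferentialMethylation,
    GeneExpression, Aging
Config/testthat/edition: 3
RoxygenNote: 7.3.3
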