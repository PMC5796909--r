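Package: cytoresponse
Title: Cytokine Response Transcriptomics: NB-GLM Differential Expression,
    Shared Response Signatures, and Regulatory Enrichment
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for multi-cytokine stimulation RNA-seq
    experiments. Implements detection filtering, TMM normalization,
    Cox-Reid trended-dispersion negative-binomial GLM likelihood-ratio
    tests with covariates, Benjamini-Hochberg FDR and fold-change DEG
    calling, treatment-by-time interaction detection, response-profile
    analytics (Spearman correlation, hierarchical clustering, principal
    component response vectors, self-organizing maps, medoid
    representatives, Chernoff-face parameter mapping, Mahalanobis
    coverage ellipses), shared-signature set logic, rank-overlap and
    cumulative-overlap enrichment statistics, GWAS SNP-proximity
    enrichment, and PWM promoter scanning with spline-adjusted logistic
    motif enrichment. A synthetic-data generator reproduces the
    statistical structure of a 4-cytokine x 2-time-point keratinocyte
    stimulation study with ground-truth tables for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    splines,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
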