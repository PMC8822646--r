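Package: fibrokinome
Title: Kinome Panel Expression Analysis of Fibrotic Lung Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for targeted kinome-panel RNA-seq analysis of
    multi-region lung tissue samples in idiopathic pulmonary fibrosis (IPF):
    RPKM normalization, median-centred hierarchical clustering of samples,
    a per-patient expression-diversity index quantifying within-patient
    heterogeneity, fold-change ranking of upregulated kinases, a
    clinically-targetable kinase subpanel filter, and a signal-to-noise
    weighted-voting classifier of histological fibrosis severity (Ashcroft
    stratum). Includes a negative-binomial synthetic-data generator that
    reproduces the study design (21 samples, 9 patients, 612-gene panel) so
    every stage is testable without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    ape,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
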