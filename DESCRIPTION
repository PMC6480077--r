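Package: miRMOR
Title: Circulating miRNA MOR-Signal Scoring for Opioid Efficacy Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing circulating microRNA qPCR panel data as
    pharmacodynamic biomarkers of mu-opioid receptor (MOR) stimulation.
    Implements detection filtering and internal-control (or global-mean)
    delta-Cq normalization of Cq panels, paired differential testing with
    Benjamini-Hochberg FDR control and common up/down signature selection
    across two opioids, the eight-miRNA MOR signal score, hierarchical
    two-class patient stratification, and association of the score and
    classes with the change in Visual Analog Scale pain intensity (delta
    VAS) under hydromorphone, via Spearman rank correlation and Fisher's
    exact test. Includes a synthetic-data generator for paired pre/post Cq
    panels with planted effects and for patient cohorts with a latent
    MOR-signal class, plus the published 25-patient marker table as a
    packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: qPCR, Normalization, Classification, Clustering, miRNA
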