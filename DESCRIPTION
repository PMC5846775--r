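Package: ProteasePanel
Title: Protease Profiling and Biomarker Panel Discovery from Gut Biopsy
    Supernatant Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis workflow for label-free proteomes of mucosal biopsy
    supernatants and the enteric-neuron responses they evoke. Provides
    variance-stabilizing (generalized-log) normalization with robust
    per-sample calibration, empirical-Bayes moderated t/F statistics with
    Benjamini-Hochberg false discovery control and abundance-pattern
    classification across healthy-control, irritable bowel syndrome and
    ulcerative colitis groups, exhaustive 2-5 protein biomarker panel search
    with linear discriminant analysis scored by repeated stratified
    train/test splits and ROC/AUC, neuroindex statistics for
    voltage-sensitive-dye and calcium-imaging ganglion recordings with the
    accompanying nonparametric test battery, and a synthetic-data generator
    that emulates the joint structure of the proteome and neurophysiology
    data for power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    MASS,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
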