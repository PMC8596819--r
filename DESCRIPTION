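Package: screendock
Title: Docking Orchestration and Virtual-Screening Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for configuring and running molecular
    docking experiments and evaluating their results. Provides a JSON-configured
    pipeline with pluggable docking backends (including a deterministic
    synthetic backend so the framework is testable end to end), ligand
    tautomer/stereoisomer enumeration and 3D embedding via Open Babel,
    best-per-ligand/best-per-enumeration/all write-out modes, sequential
    benchmarking of many configurations, and an analysis suite covering
    virtual-screening enrichment (logarithmic ROC AUC), rank correlation with
    ties (Spearman, Kendall tau-b), and threshold-based classification reports.
    Also implements the scoring machinery used when docking steers a generative
    molecular-design agent: score transforms onto [0,1], weighted geometric
    mean multi-parameter aggregation, a scaffold-bucket diversity filter, and
    epoch-wise average-linkage Tanimoto similarity analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    ChemmineR,
    ChemmineOB,
    parallel,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
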