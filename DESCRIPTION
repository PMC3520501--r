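Package: seqhts
Title: Sequential Stopping for High-Throughput Group-Comparison Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-theoretic sequential sample-size determination for
    high-throughput two-group comparison experiments (microarray, RNA-seq,
    reverse-phase protein arrays). Implements empirical-Bayes hierarchical
    mixture models for differential expression (the gamma-gamma model and the
    log-normal-normal model with generalized variance), terminal decisions
    that control the posterior expected false discovery rate, and sequential
    stopping rules based on the one-step-ahead expected gain in true
    positives.  Linear stopping boundaries are evaluated and optimized by
    forward simulation from the posterior predictive distribution, and
    study-level operating characteristics (stopping time, realized FDR,
    expected utility) are estimated by simulation, including under prior
    misspecification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    pracma,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: ExperimentalDesign, DifferentialExpression, Bayesian,
    MultipleComparison, Microarray, RNASeq, Proteomics
RoxygenNote: 7.3.3
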