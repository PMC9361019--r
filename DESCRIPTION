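Package: StemSig
Title: Transcriptomic Stemness Index and Drug-Response Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an end-to-end stemness-index analysis for bulk tumor
    transcriptomes: a one-class logistic regression (OCLR) model with elastic-net
    penalties trained on a stem-cell reference compendium, rank-correlation
    scoring of tumor samples (mRNAsi), median-split differential expression with
    Monti consensus clustering into stemness subgroups, hypergeometric
    over-representation and preranked gene set enrichment analysis, bootstrap
    score-based Bayesian-network inference over pathway activities, a PCA-based
    four-gene response signature with an ROC-derived cutoff, and Kaplan-Meier /
    Cox survival stratification. A synthetic-data module generates reference and
    cohort data with planted stemness, response and regulatory-chain structure so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    SummarizedExperiment,
    mclust,
    fgsea,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
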