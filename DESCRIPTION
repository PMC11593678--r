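Package: FolrSig
Title: Pooled Transcriptomic Analysis of FOLR1 Expression and a
    Prognostic FOLR1-High-Like Signature in Ovarian Cancer
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to harmonize multi-platform ovarian cancer expression
    cohorts (quantile normalization, most-variant-probe collapse, per-dataset
    standardization against a primary tumor reference), dichotomize a target
    gene (FOLR1 by default) at the pooled-series median, run an
    empirical-Bayes moderated-t differential expression analysis with
    p-value, false discovery rate and fold-change gates, build a
    median-centroid "high-like" metagene signature and classify independent
    samples by the sign of their Pearson correlation with the centroid, and
    evaluate clinicopathological associations (odds ratios, Fisher exact,
    t-test, ANOVA) and survival (Kaplan-Meier, log-rank, Cox regression with
    Wald tests, time-stratified and interaction models). A synthetic
    multi-cohort data generator with planted signature genes, covariate odds
    ratios and proportional-hazards survival makes the full pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    yaml,
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, DifferentialExpression, Survival, Classification
RoxygenNote: 7.3.3
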