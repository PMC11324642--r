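Package: floodgene
Title: Multi-Method Selection of Waterlogging-Responsive Genes with
    Differential Gene Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for identifying stress-responsive genes from a
    two-condition RNA-seq count matrix, built around the analysis of cucumber
    (Cucumis sativus) under waterlogging stress. Median-of-ratios count
    normalization is followed by four attribute-weighting gene selectors
    (symmetric uncertainty, Relief, Pearson correlation, linear-SVM
    hyperplane weights), L1-penalized logistic regression with the
    one-standard-error rule, differential gene correlation analysis based on
    the Fisher z-transformation, and validation of the consensus panel with
    random forests, additive Shapley attributions and a shadow-feature
    (Boruta-style) confirmation loop. A negative-binomial simulator with
    planted differential expression and planted condition-specific
    correlation blocks provides ground-truthed synthetic data for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    glmnet,
    jsonlite,
    pROC,
    ranger,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
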