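Package: perturbbench
Title: Benchmarking Baselines and Diagnostics for Post-Perturbation
    Expression Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking predictors of post-perturbation RNA-seq
    profiles on Perturb-seq-style data. Implements pseudo-bulk aggregation and
    differential (delta) expression profiles, perturbation-exclusive
    train/validation/test splitting with combo subgroup labels, differential
    expression ranking (Welch t and Wilcoxon) with top-K selection and CRISPR
    target exclusion, baseline predictors (train mean, random forest, elastic
    net, k-nearest neighbours) over PCA-reduced gene-embedding features, the
    Pearson-delta family of evaluation metrics, dataset-heterogeneity
    diagnostics (pairwise delta correlations and benchmark dynamic range), and
    a derangement-permutation test for the pathway coherence of gene
    embeddings. A synthetic Perturb-seq generator with controllable
    heterogeneity makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    ranger,
    stats,
    utils,
    withr
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
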