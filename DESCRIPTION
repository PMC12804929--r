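Package: pqtlgap
Title: Detecting Non-Linear Genetic and Covariate Effects on Quantitative Molecular Traits
Version: 0.1.0
Authors@R: person("pqtlgap", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for detecting non-linear covariate effects,
    genetic dominance, and epistasis influencing quantitative molecular traits
    such as plasma protein levels. Compares a flexible non-linear genomic
    predictor (a locally connected neural network with integrated-gradients
    attribution and Bayesian-optimized variant selection) against a penalized
    linear elastic-net baseline, and decomposes any performance gap with
    paired-bootstrap model comparison, per-genotype non-additivity tests, a
    pairwise epistasis scan with Bonferroni control, iterative complexity
    analysis, and interaction-constrained gradient boosting. Includes a
    synthetic-data module (Hardy-Weinberg genotype draws with optional LD
    blocks, configurable additive, dominance, epistatic, GxE, ExE and
    non-linear covariate components), PLINK1 bed/bim/fam input and output,
    and the standard quality-control and rank-based inverse normal
    transformation procedures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
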