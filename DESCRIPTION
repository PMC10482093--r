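Package: dietGxE
Title: Weighted Food Scores and Gene-Diet Interaction Analysis for
    Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for diet-quality scoring and gene-diet interaction
    analysis in case-control studies of type 2 diabetes. Implements the
    46-point Recommended Food Score (RFS) from food-frequency questionnaire
    categories, two weighted food scores -- a ridge-penalized hierarchical
    structural component logistic model (HisCoM-RFS) fitted by alternating
    least squares with permutation inference, and a partial-least-squares
    discriminant score (PLSDA-RFS) -- together with covariate-adjusted
    association models, diet-quality tertiles, per-SNP score-by-genotype
    interaction scans, simplified gene and gene-set aggregation with
    Benjamini-Hochberg correction, polygenic-risk-score stratification and
    the 3x3 genetic-risk by diet-quality interaction grid. A seeded
    synthetic cohort generator with planted item weights, group
    coefficients and interaction effects makes every stage testable
    without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
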