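---
title: "Weighted food scores and gene-diet interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted food scores and gene-diet interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietGxE)
```

## The scientific problem

Diet-quality indices such as the Recommended Food Score (RFS) tally how
many recommended, antioxidant-rich foods a person eats regularly. The RFS
treats every food equally: one point per item consumed at least once a
week, plus one point for a regular three-meals-a-day pattern, for a total
of 0-46 points across ten food groups (meals 1, grains 1, legumes 4,
vegetables 16, seaweeds 2, fruits/juices 12, fish 5, dairy 3, nuts 1,
tea 1). Equal weighting is a strong assumption -- some foods plausibly
matter more than others for a metabolic outcome like type 2 diabetes
(T2D). This package implements two *weighted* food scores that learn
item-level weights from a case-control outcome, and the downstream
gene-diet interaction analyses those scores feed: covariate-adjusted
association, diet-quality tertiles, a per-SNP score-by-genotype
interaction scan, gene- and gene-set-level aggregation, and the 3x3
genetic-risk by diet-quality grid built on a polygenic risk score (PRS).

Because the cohort data this style of analysis targets are
access-restricted, the package ships a first-class synthetic cohort
generator with planted ground truth, so every stage is testable and the
whole pipeline runs end to end on simulated data.

## The hierarchical structural component model

The HisCoM-weighted score treats the 46 binary item indicators
$g_{itk}$ (item $t$ of group $k$, subject $i$) as forming latent group
components. Item weights $w_{tk}$ combine items into their group
component, and group coefficients $\beta_k$ connect components to the
outcome through a logistic link:

$$\operatorname{logit}(\pi_i) = \beta_0 + \sum_{k=1}^{K}
  \Big[\sum_{t=1}^{T_k} g_{itk} w_{tk}\Big]\beta_k,$$

and the per-subject weighted score is the same linear combination
without the intercept:

$$\text{HisCoM-RFS}_i = \sum_{k=1}^{K}
  \Big[\sum_{t=1}^{T_k} g_{itk} w_{tk}\Big]\beta_k.$$

Estimation is by alternating least squares (ALS) wrapped in an
iteratively reweighted (IRLS) loop for the logistic link: Step 1 fixes
the item weights and updates $(\beta_0, \beta)$ by weighted least
squares on the working response; Step 2 fixes $\beta$ and updates all
item weights jointly by a ridge-penalized weighted least-squares solve.
The ridge penalty $\lambda_1$ applies to the item weights only; the
group coefficients are unpenalized ($\lambda_2 = 0$), so the outcome
stays a linear combination of the food items rather than of shrunken
group summaries.

### Identification and numerical choices

The model is scale-unidentified: multiplying a group's weights by $c$
and its coefficient by $1/c$ leaves the likelihood unchanged (and with
$\lambda_2 = 0$ an unconstrained optimizer would drive
$\|w\| \to 0$). We therefore adopt the standard structured-component
conventions:

* item columns are divided by their sample standard deviation (but not
  centered -- this keeps the score formula exact at $g = 0$, so an
  all-zero response scores 0);
* after every sweep each group component is rescaled to unit sample
  variance, absorbing the scale into $\beta_k$;
* signs are fixed so each group's weights sum to a nonnegative value.

With a single standardized item in a group this forces $w = \pm 1$ and
$\beta \cdot w$ equals the slope of an ordinary univariate logistic
regression -- the oracle the test suite checks to $10^{-6}$.

The penalized deviance $-2\ell + \lambda_1\|w\|^2$ is evaluated on the
constrained (renormalized) iterate after each sweep. A step-halving
backtrack guards the descent: if a full ALS step increases the
objective, the update is shrunk toward the previous iterate until the
objective is non-increasing (tolerance $10^{-8}$ per iteration; the
test suite asserts the whole trace). Convergence is declared when the
maximum relative parameter change falls below $10^{-6}$ (default), with
a 500-iteration cap; in practice fits converge in well under ten sweeps.
Constant item columns are an error at $\lambda_1 = 0$ (the update is
singular) and are tolerated -- with their weight shrunk to zero -- when
$\lambda_1 > 0$.

$\lambda_1$ has no published value, so the default policy is 5-fold
cross-validation over a small grid, scored by held-out binomial
deviance with ties resolved to the smaller penalty
(`select_lambda1()`).

### Permutation inference

Parameter significance uses phenotype-resampling permutations: the model
is refit under `B` random permutations of the outcome and each group
coefficient and item weight gets
$p = (1 + \#\{|\hat\theta_{perm}| \ge |\hat\theta_{obs}|\})/(B + 1)$.
Both the group-level and item-level p-values are reported, since either
level may be of interest. `B = 999` is the recommended reporting
default; calibration tests run at reduced `B` for speed. Under the null
these p-values are uniform, which the acceptance suite verifies over
200 replicate datasets (KS test).

## The PLS-DA weighted score

The second weighted score ignores the group structure entirely: NIPALS
partial-least-squares regression of the centered 0/1 outcome on the
centered indicator matrix. The first weight direction is the normalized
cross-covariance $X_c^\top (y - \bar y)$ -- the direction maximizing
covariance between component scores and the outcome -- and successive
components are extracted after deflation (score vectors mutually
orthogonal). The per-subject PLSDA-RFS multiplies the subject's item
indicator vector by the per-item coefficient vector
$W(P^\top W)^{-1}q$ (the first -- and with a univariate outcome, only --
column of the coefficient matrix). The published recipe is ambiguous
about whether the "RFS scores" entering that product are the scalar
totals or the item vectors; the scalar reading is non-conformable with a
46-row weight matrix, so the item-vector reading is implemented. One
component is the default since only the first coefficient column feeds
the score; the component count is exposed as a parameter.

## Downstream analyses

* **Baseline table** (`build_table1()`): Welch t-tests for continuous
  variables (pooled available; both reproduce two-decimal published
  summaries within $\pm 0.01$) and Pearson chi-squared for categorical
  ones, with the Yates continuity correction applied exactly for 2x2
  tables -- the convention required to reproduce published 2x2
  p-values. `t_test_summary()` works from (mean, SD, n) so printed
  tables can be re-analyzed without subject-level data.
* **Association** (`fit_association()`): logistic regression of the
  outcome on the standardized score plus the ten adjustment covariates
  (age, sex, area, BMI, smoking, alcohol, coffee, education, income,
  METs), reporting Wald odds ratios with 95% CIs. Perfect separation
  and collinear covariates are explicit errors, not silent results.
* **Tertiles** (`tertile_groups()`): percentile rank $(r - 0.5)/n$ with
  average ranks for ties (tied subjects are never split across groups),
  cut at thirds. Reported cut percentages of 33.33%/66.6% are the
  rounded thirds; the exact values are used so tie-free groups have
  size $n/3$ within one.
* **Interaction scan** (`interaction_scan()`): per SNP, logistic
  `y ~ covariates + score + snp + snp:score`, recording the product
  term (the SNP main effect is included, standard hierarchical-
  interaction practice and what PLINK's interaction test does).
  Monomorphic and MAF < 0.05 SNPs are skipped with recorded reasons.
* **Gene and gene-set aggregation** (`gene_test()`,
  `gene_set_test()`): a deliberately simplified analogue of gene-based
  GWAS aggregation -- principal components capturing 95% of the gene's
  genotype variance replace its SNPs and all PC-by-score interaction
  terms are tested jointly by likelihood ratio; alternatively a
  Sidak-style combination of per-SNP p-values with the Li-Ji effective
  number of tests. Gene-set enrichment is competitive: gene z-statistics
  (probit-transformed p-values) regressed on set membership, one-sided,
  with Benjamini-Hochberg correction across sets. These are functional
  stand-ins, not reimplementations of external gene-set software, and
  their defaults (95% variance, gene-body mapping with an optional
  +/-kb window) are documented rather than claimed equivalent.
* **PRS and the risk grid** (`compute_prs()`, `risk_by_diet_grid()`):
  the PRS is a plain weighted allele sum after effect-allele
  harmonization (allele-flip invariant; unresolvable SNPs are excluded
  with a count). LD-aware reweighting of external summary statistics is
  out of scope; a causal-fraction tuning parameter from such tools
  would be metadata only. PRS tertiles use the same rank rule as diet
  tertiles, and the 3x3 grid is dummy-coded against the (low genetic
  risk, high diet quality) reference cell.

## What the synthetic cohort emulates

`simulation_config()` defaults describe a cohort of 4,292 subjects with
1,090 cases (case fraction 0.254), ages 40-69, and FFQ category
probabilities giving a weekly-or-more probability of 0.37 per item --
hence a mean unweighted RFS near 17/46, matching the cohort the
analysis is designed for. Genotypes are Hardy-Weinberg draws at MAFs in
[0.05, 0.5] (the post-QC range). The phenotype follows the hierarchical
model above: standardized group components times planted group
coefficients, plus covariate effects, plus optional planted
SNP-by-score interaction terms; the intercept is tuned by bisection so
the expected case fraction hits its target.

Deliberately *not* emulated: correlations between food items,
covariate joint structure (independent marginals only), linkage
disequilibrium between SNPs, and follow-up waves. Passing tests on this
generator therefore demonstrate correctness of the estimators under
the model's own assumptions -- not robustness to real FFQ correlation
structure or LD.

Two planted-signal regimes are used in validation, fixed as part of the
experimental design:

* **Weight-recovery regime** (the generator default): group
  coefficients `seq(0.3, 0.6)` per component SD and within-group item
  weights spaced 0.4-1.6. This is a strong, well-powered planted diet
  signal -- intentionally stronger than typical observed diet-T2D
  associations -- because item-level weights are only estimable at
  n = 4,000 when the group signals are clearly detectable. Recovery is
  measured as the correlation between fitted and planted absolute
  weight patterns on the identified scale (unit within-group L2 norm),
  since single-item groups carry no free weight and overall group
  scale is absorbed by the identification constraints.
* **Interaction-power regime**: group coefficients `rep(0.1, 10)`,
  i.e. a total diet main effect near the per-SD odds ratios actually
  reported for diet scores (~1.1), with the planted interaction
  log-OR 0.3 at MAF 0.3. A very strong diet main effect would spread
  the linear predictor and is not the condition the power statement
  refers to.

Problem sizes used by the test and acceptance suites -- chosen as
representative desk-scale experiments -- are: n = 4,000 cohorts for
recovery (10 seeds) and power (20 seeds, one planted SNP each), 500
null SNPs at n = 2,000 for type-I calibration, and 200 replicate
null datasets (n = 150, 8 items, B = 39) for permutation calibration.

## Known limitations

* The 45 concrete food items of the published panel are not public;
  the default panel is a schema-level template with the correct group
  sizes, and studies supply their own item list.
* The gene/gene-set stage is a simplified analogue (see above), and the
  PRS is an unweighted-LD allele sum.
* Real-data odds ratios, gene lists and pathway q-values from
  restricted cohort data are not reproduction targets; the package's
  claims are about estimator correctness, calibration and power under
  the documented synthetic conditions.
* Published HisCoM-RFS summaries are consistent with scores on a
  centered scale; this implementation's score is uncentered by design
  (exact at the origin). Downstream analyses standardize scores, so
  association results are unaffected by this affine difference.
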