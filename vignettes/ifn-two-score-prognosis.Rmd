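---
title: "A two-score interferon system and the prognosis of progression to connective tissue disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-score interferon system and the prognosis of progression to connective tissue disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifnprog)
```

## The scientific problem

Antinuclear antibodies (ANA) can be detected years before any autoimmune
connective tissue disease (CTD) becomes clinically manifest, but most
ANA-positive people never progress. A clinic that sees referred
ANA-positive, treatment-naive individuals with at most one clinical
lupus criterion ("At-Risk" individuals) therefore needs prognostic
markers: who, within a year, will meet classification criteria for
lupus, Sjogren's syndrome or another CTD?

Type-I interferon activity is the leading candidate. It is measured
indirectly, through the expression of interferon-stimulated genes
(ISGs) in blood, by quantitative RT-PCR. `ifnprog` implements a
two-score system over a panel of 30 ISGs — a Score-A set dominated by
classical type-I-responsive genes and a Score-B set of more broadly
(type II/III as well as type I) responsive genes — together with the
complete statistical pipeline needed to evaluate those scores as
prognostic biomarkers and to model 12-month progression.

## qPCR arithmetic and sign conventions

The raw measurement is a cycle threshold `Ct` per gene and sample.
Normalisation against a housekeeping reference gene (peptidylprolyl
isomerase A) gives

$$\Delta Ct_{g,s} = Ct_{g,s} - Ct_{\mathrm{ref},s},$$

implemented by `delta_ct()`. One cycle is one doubling, so relative
expression is $2^{-\Delta Ct}$ (`relative_expression()`) and a
between-group contrast of mean $\Delta Ct$ converts to a fold
difference $FD = 2^{-\Delta\Delta Ct}$ (`fold_difference()`).
Throughout the package **higher $\Delta Ct$ means lower expression**;
wherever a regression or correlation wants "bigger = more interferon"
the *reflected* value $-\Delta Ct$ is used (`reflect()`, and the
`reflected` flag on score objects). Cutoffs, however, are quoted in raw
$\Delta Ct$ units so that a published threshold such as
"$\le 5.01\ \Delta Ct$" is directly usable (`classify_scores()` is
inclusive: a score exactly at the cutoff is positive).

Confidence intervals for fold differences are computed on the
$\Delta\Delta Ct$ scale and then exponentiated, so they are exact
monotone transforms of t-intervals. The default is Welch
(unequal-variance) for two-group contrasts; `method = "pooled"`
restores the equal-variance Student interval, and `method = "tukey"`
uses the studentised-range critical value and pooled mean square from a
one-way ANOVA when the contrast sits inside a three-group comparison
(healthy controls / At-Risk / SLE). Both flavours are exposed because
the multiplicity treatment of published fold-difference intervals is
not stated; the pipeline reports the Tukey-context interval for
three-group contrasts and Welch for the progressor contrast. Missing
$\Delta Ct$ values are excluded pairwise from group means, consistent
with expression data missing for technical (not biological) reasons.

## From 30 genes to two scores

`fit_factor_model()` performs principal-axis factoring on the
gene-gene correlation matrix of reflected $\Delta Ct$ (complete samples
only), with communalities initialised at squared multiple correlations
and iterated to convergence (tolerance `1e-7` on the communalities, at
most 200 sweeps), followed by varimax rotation. Principal-axis
factoring with varimax is the conventional choice for deriving gene
modules when the interest is in a simple loading structure; the
rotation spreads variance across factors, so the object also keeps the
*unrotated* eigenvalues for judging dimensionality.

`assign_genes()` sends each gene to the factor with the larger absolute
loading provided it reaches the loading threshold (default 0.4, the
usual "salient loading" convention); ties go to Score-A, genes below
the threshold stay unassigned. In routine use the partition is *fixed*:
a published gene list is supplied via `gene_partition()` or a partition
JSON, and factor fitting is bypassed. This mirrors how the two-score
system is deployed in practice — the factor solution was derived once,
on reference cohorts, and then applied unchanged.

A sample's score on a set is the **median** reflected-or-raw
$\Delta Ct$ of the set's observed genes (`compute_scores()`; even
cardinality averages the central pair). The median is robust to a
single failed assay. A score is only reported when at least half of the
set's genes (rounded up; configurable) were observed — below that floor
a median of leftovers is not comparable across samples and the score is
set to `NA` with a warning.

## Biomarker evaluation

`ifn_roc()` sweeps every observed score as a candidate cutoff with the
same inclusive rule the classifier uses, so the reported operating
points are exactly attainable in the data. The AUC is the trapezoid
area, which equals the Mann-Whitney probability with ties counted one
half; its confidence interval and the paired comparison of Score-A
against Score-B (`compare_auc_paired()`) use the DeLong variance, with
the paired statistic reported as $\chi^2 = z^2$ on 1 df.

Two cutoff policies are provided. `youden_cutoff()` maximises
$J = \mathrm{sens} + \mathrm{spec} - 1$, breaking exact ties toward
higher sensitivity (for a screening use, missing a future progressor is
the costlier error). `rule_in_cutoff()` returns the most sensitive
observed cutoff whose specificity meets a floor (default 0.80) — the
operating point one wants when enrolling a prevention trial, where
false positives dilute the treated population. The artificial
"call nobody positive" end of the curve is not an operating point and
is excluded; if no observed cutoff reaches the floor the function
errors, reporting the best achievable specificity.

`diagnostics()` derives sensitivity, specificity, PPV and NPV from the
confusion counts, each with a two-sided 95% **Wilson score interval
without continuity correction**. That choice is deliberate: among the
standard binomial intervals, the uncorrected Wilson interval is the one
whose endpoints, rounded to integer percentages, reproduce every
published interval this package's acceptance checks target (for
example 18/19 gives 75–99%, 52/53 gives 90–100%, 7/21 gives 17–55%).
Percentages are displayed rounded to integers, matching clinical
reporting style; raw proportions are retained in the object.

## Cohort statistics

Clinical criteria counted at baseline and at 12 months form a paired
square table; whether the marginal distribution shifted is the
Stuart-Maxwell question. `stuart_maxwell()` computes
$\chi^2 = d' S^{-1} d$ on the marginal differences with one category
dropped; for two categories this is exactly McNemar's
$(b-c)^2/(b+c)$ **without** continuity correction. Structural zeros
(e.g. every progressor starting from exactly one criterion) can make
$S$ singular for some choices of dropped category, so the
implementation drops the category with the smallest combined marginal
sum and falls back to a Moore-Penrose inverse — with degrees of freedom
equal to the rank — if singularity persists. The statistic is invariant
to which category is dropped whenever the reduced matrix is
invertible.

The remaining comparisons go through the standard machinery: one-way
ANOVA with Tukey honest-significant-difference contrasts
(`anova_tukey()`), Fisher's exact test (`fisher_exact()`), Kendall's
tau-b for ordinal associations with ties (`kendall_tau_b()`, normal
approximation for the p-value) and Pearson correlation (`pearson_r()`).
All p-values are two-sided.

## Multiple imputation

In the motivating design, expression is missing for a block of samples
that were simply not processed on the day — whole-profile, missing
completely at random. `impute_chained()` implements multiple imputation
by chained equations with the two classical univariate engines:
predictive mean matching (Bayesian parameter draw, five donors) for
continuous variables and a Bayesian logistic draw for binary ones,
each conditioning on all other variables including the outcome.
Defaults are `m = 20` completed datasets and 10 sweeps; a master seed
spawns one sub-stream per imputation, so results are bit-reproducible.
A variable less than half observed is refused — with worse coverage
the chained regressions mostly model other imputations.

`pool_rubin()` combines per-imputation estimates: pooled point
estimate = mean, total variance $T = W + (1 + 1/m)B$, inference on
Barnard-Rubin adjusted degrees of freedom when the complete-data df is
supplied (the classical $(m-1)(1+W/((1+1/m)B))^2$ otherwise).

## The penalised prognostic model

`fit_prognostic()` reproduces the full modelling sequence on an
At-Risk table (covariates plus reflected scores):

1. chained-equation imputation of incomplete predictors;
2. univariable screening — a single-covariate logistic fit per
   predictor per imputation, pooled by Rubin's rules; predictors with
   pooled $p > 0.10$ are excluded (separation is caught and refitted by
   Firth's bias-reduced logistic regression);
3. a pooled unpenalised multivariable logistic model over the retained
   set, reported as odds ratios with Rubin intervals;
4. per imputation, an L1-penalised logistic model.

The lasso (`lasso_logistic()`) minimises
$\frac{1}{n}\sum_i -\ell_i(\beta_0,\beta) + \lambda \lVert\beta\rVert_1$
by cyclic coordinate descent on the IRLS quadratic approximation, with
the intercept unpenalised and predictors standardised internally to
population unit variance (so the penalty is symmetric; coefficients are
reported back on the original scale). Convergence requires the largest
coefficient change in a full IRLS sweep to fall below `1e-7`. The
default path has 100 log-spaced penalties from just above
$\lambda_{\max} = \max_j |X_j'(y-\bar y)|/n$ (where the null model is
exact by the Karush-Kuhn-Tucker conditions — the "just above" absorbs
floating-point equality at the boundary) down to
$10^{-3}\lambda_{\max}$. At $\lambda \to 0$ the fit agrees with the
Newton-Raphson maximum-likelihood solution; the test suite checks both
ends and the KKT conditions along the path, and cross-checks whole
paths against an independent implementation.

`cv_lasso_logistic()` scores the path by leave-one-out
cross-validation: mean held-out binomial deviance (probabilities
clipped at $10^{-8}$ so a degenerate fold cannot produce an infinite
deviance) with its standard error, selecting both the minimiser and
`lambda_1se` — the largest penalty within one standard error of the
minimum. The 1-SE rule is the parsimony convention used for the
prognostic model; leave-one-out rather than 10-fold because with 19
events the fold-to-fold variance of stratified k-fold is substantial.

Across imputations, the per-imputation `lambda_1se` coefficients are
**averaged**, and the mean coefficient is exponentiated into an odds
ratio; the across-imputation minimum and maximum are retained
alongside. (Averaging the best per-imputation models and then
transforming the averaged coefficient is the reading consistent with
how penalised results are tabulated in the motivating analysis — each
tabulated pair is a coefficient and exactly its exponential.) Because
the lasso shrinks, penalised odds ratios are deliberately conservative
relative to the pooled multivariable estimates; predictors that rarely
survive `lambda_1se` average to nearly zero.

## The synthetic cohort generator

No individual-level data ship with the package; `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes,
and `cohort_config()` pins the default study conditions: 118 At-Risk
(16% expected progression), 49 healthy controls, 114 SLE; 30 ISGs (15
per score set); whole-sample expression missingness 13/118 among
At-Risk only; reference Ct fixed at 20 cycles.

Each sample carries two correlated latent factors on the reflected
score scale. A gene's reflected $\Delta Ct$ is
$\mathrm{loading} \times \mathrm{factor} + \varepsilon$ with loading
0.9 and Gaussian noise of 0.8 cycles — noise on the cycle (log2) scale
is the natural qPCR error model. The latents are parameterised so that
the configured means and SDs are what the median *scores* realise (the
loading rescales the factor internally).

Group means are anchored to the published fold differences: healthy
controls at $(-6.16, -4.96)$ for (A, B), SLE at $(-3.19, -3.01)$, and
At-Risk placed so that *non-progressors* average $-5.3$ on both scores
(the published non-progressor mean). Progression is drawn from a
logistic model
with exactly the two configured effects — family history of autoimmune
rheumatic disease at OR 8.2 and the Score-B latent at OR 3.79 per
reflected unit — with the intercept calibrated numerically so the
expected progression fraction is 16%. The Score-B SD of 1.4 (also the
published non-progressor SD) was calibrated by Monte Carlo so that the
*selection-induced* progressor/non-progressor contrast equals the
published 3.22-fold difference at 16% prevalence; the naive
rare-outcome approximation $\beta\sigma^2$ understates the required SD
at this prevalence. The A–B correlation of 0.68 propagates a 2.94-fold
contrast to Score-A, which has no direct effect on progression —
matching the observation that Score-A's association vanishes in the
multivariable model. Other covariates are drawn from the published
baseline summaries but are independent of progression: their real
correlation structure is unreported, so independence plus the two
configured effects is the assumption, stated here explicitly.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: covariate–covariate correlation
(e.g. age with smoking), non-Gaussian score distributions, PCR
efficiency differences between assays, informative (non-MCAR)
missingness, misclassified outcomes, and any skin-biopsy tissue
effect. Results on synthetic cohorts validate the *machinery* at the
study's effect sizes, not the biology.

## Problem sizes and reproducibility

The test suite exercises the full pipeline at the study scale
(n = 118 At-Risk, m reduced to 2–5 imputations in most end-to-end
blocks) and averages stochastic properties over 5–40 seeded
replicates; parameter-recovery properties use synthetic cohorts of
n = 1000 with the penalised stage switched off, since they concern the
pooled multivariable estimates. These sizes were chosen so that every
property is decisively testable while the whole suite stays fast
enough to run habitually. `scripts/acceptance.R` recomputes, from the
installed package alone, the desk-scale published quantities
(criteria-transition $\chi^2$, the diagnostic metrics and Wilson
endpoints at both cutoffs, ultrasound predictive values) and the
synthetic end-to-end quantities (fold differences, AUCs, odds-ratio
recovery), all from a single command-line seed.

## Known limitations

* The Stuart-Maxwell statistic on the progressor-style table (all
  subjects entering from one category) is 19.0 by the standard
  marginal-homogeneity formula; published analyses of such tables
  sometimes report slightly different values depending on the variant
  used, and no variant option is provided.
* The chained-equation imputer supports numeric and binary variables
  only — the covariate set needs nothing more — and does not implement
  multilevel or ordinal engines.
* `fold_difference()` assumes approximate normality of $\Delta Ct$
  within groups; with a handful of samples (skin biopsies, say) the
  t-based interval is only indicative, as the bootstrap comparison in
  the test suite illustrates.
* The penalised model reports no p-values: shrinkage invalidates the
  usual Wald machinery, which is why the unpenalised pooled model is
  reported alongside.
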