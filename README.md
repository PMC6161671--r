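# ifnprog

Two-score interferon status and the prognosis of progression from
ANA-positive "At-Risk" status to autoimmune connective tissue disease
(CTD).

## What this package is for

Antinuclear antibodies precede clinical autoimmunity by years, but most
ANA-positive individuals never develop disease. For a cohort of
treatment-naive, ANA-positive individuals with at most one clinical
lupus criterion, the prognostic question is which of them will meet CTD
classification criteria within 12 months. Interferon activity, read out
as interferon-stimulated gene (ISG) expression by qRT-PCR, is the
central biomarker candidate.

`ifnprog` implements, as tested reusable components, a two-score ISG
system and the complete analysis pipeline around it:

* **qPCR arithmetic** — reference-gene normalisation
  ΔCt = Ct_gene − Ct_ref, relative expression 2^−ΔCt, and group
  contrasts as fold differences FD = 2^−ΔΔCt with t-based (Welch,
  pooled, or Tukey-context) confidence intervals computed on the ΔΔCt
  scale and exponentiated.
* **Two-score derivation** — principal-axis factor analysis with
  varimax rotation partitions the 30 ISGs into a Score-A and a Score-B
  gene set (`fit_factor_model()`, `assign_genes()`); in routine use a
  fixed published partition is supplied instead. A sample's score is
  the **median ΔCt of its set's observed genes**
  (`compute_scores()`), classified against inclusive ΔCt cutoffs
  (`classify_scores()`).
* **Cohort statistics** — Stuart–Maxwell marginal-homogeneity test
  χ² = d'S⁻¹d for paired criteria transitions (McNemar (b−c)²/(b+c)
  for 2×2, no continuity correction), one-way ANOVA with Tukey HSD,
  Fisher's exact test, Kendall tau-b, Pearson correlation.
* **Biomarker evaluation** — ROC curves over observed cutoffs with
  Mann–Whitney/trapezoid AUC and DeLong intervals, paired DeLong
  comparison of two scores, Youden-optimal and specificity-floor
  ("rule-in") cutoffs, and confusion-matrix diagnostics with Wilson
  score intervals (`ifn_roc()`, `youden_cutoff()`, `rule_in_cutoff()`,
  `diagnostics()`).
* **Prognostic modelling** — multiple imputation by chained equations
  (PMM + Bayesian logistic draws), univariable screening at the 10%
  level pooled by Rubin's rules, a pooled multivariable logistic
  model, and per-imputation L1-penalised logistic regression
  (coordinate descent, leave-one-out cross-validation, 1-SE rule) with
  coefficients averaged across imputations (`fit_prognostic()`).
* **Synthetic cohorts** — `simulate_cohort()` generates cohorts with
  the study's statistical structure (group-shifted latent factors,
  configured progression odds ratios, MCAR whole-sample expression
  missingness) so every stage is testable end-to-end without any data
  download.

## Worked example

Generate a default synthetic cohort (118 At-Risk, 49 healthy controls,
114 SLE), score it, and run the prognostic analysis:

```r
library(ifnprog)

co     <- simulate_cohort(cohort_config(seed = 7))
dct    <- delta_ct(co$expression)                     # warns: 13 samples missing
scores <- compute_scores(dct, co$truth$partition)
tab    <- cohort_table(co, scores)                    # At-Risk modelling table

roc_b <- ifn_roc(-tab$ifn_score_b, tab$progression)   # raw dCt, lower = positive
roc_b
#> ROC: AUC = 0.807 (95% CI 0.703 to 0.911); 17 positives, 88 negatives

youden_cutoff(roc_b)
#> Youden cutoff: positive when score <= 5.222 (Youden J = 0.47)
#> Confusion: TP=17 FP=47 FN=0 TN=41
#>   sensitivity  100% (82% to 100%)
#>   specificity   47% (37% to 57%)
#>   ppv           27% (17% to 38%)
#>   npv          100% (91% to 100%)
#>   Youden J     0.47

fold_difference(-tab$ifn_score_b[tab$progression == 1],
                -tab$ifn_score_b[tab$progression == 0],
                groups = c("progressors", "non-progressors"))
#> Fold difference (progressors vs non-progressors): 2.68 (95% CI 1.79 to 4.01), p=3.69e-05
#>   ddCt = -1.42 cycles; n = 17/88; welch

fit <- fit_prognostic(tab, m = 20, seed = 7)
fit
#> Prognostic model of progression (multiple imputation + penalised logistic regression)
#>   n = 118, events = 21, m = 20 imputations, screening alpha = 0.10
#>   Excluded at screening: age, ever_smoked, n_ana_specificities, c4, lymphocytes, us_positive_joints, patient_vas, physician_vas
#>   Multivariable (pooled) and penalised estimates:
#>     family_history_ard         OR   7.98 ( 2.01 to  31.61), p = 0.00347   penalised 0.362 -> OR 1.436
#>     ifn_score_a                OR   1.09 ( 0.69 to   1.71), p = 0.718     penalised 0.013 -> OR 1.013
#>     ifn_score_b                OR   4.54 ( 1.81 to  11.43), p = 0.00158   penalised 0.580 -> OR 1.786
```

Reading the output: Score-B separates future progressors from
non-progressors (AUC 0.81; a 2.7-fold higher baseline expression in
progressors), and after imputation and screening only family history of
autoimmune rheumatic disease and IFN-Score-B remain independently
associated with progression — the structure the generator was
configured to produce (true odds ratios 8.2 and 3.79). The penalised
column shows the shrunken coefficients averaged over imputations; the
uninformative Score-A survives screening only through its correlation
with Score-B and is shrunk to near zero.

`run_pipeline(cohort_config(seed = 7))` runs the same sequence —
ΔCt → partition → scores → group fold differences → ROC and cutoffs →
imputation → screening → lasso → pooling — in one call and can write a
machine-readable report (`out_dir = ...`).

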