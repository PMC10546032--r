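# lactpair

Rank-based gene-pair prognostic indices for censored survival outcomes.

## The problem

Expression-based prognostic signatures usually break when moved between
platforms: microarray intensities, RNA-seq FPKM and TPM live on different
scales, and per-cohort normalisation changes every absolute value. A
signature built on *within-sample gene orderings* sidesteps this entirely.
For a pair of genes (Gi, Gj) measured in the same sample,

    Score_ij = 1  if  Gi > Gj,   0 otherwise,

so each feature is a binary indicator that depends only on which of the two
genes is expressed higher in that sample. Any strictly increasing
per-sample transformation — rescaling, log transforms, quantile shifts —
leaves every score unchanged, so a frozen signature transfers across
platforms without renormalisation.

`lactpair` builds and evaluates such indices for censored survival data.
The construction, given an expression matrix, a clinical table and a
candidate gene universe:

1. exclude samples followed up for less than 1 month;
2. univariate Cox screen of candidate genes (Wald p < 0.05);
3. enumerate pairs (prognostic gene first) and encode the binary pair
   score matrix;
4. drop near-constant pairs — score identical in **more than 70%** of
   samples (a pair at exactly 70% is kept);
5. univariate Cox screen of the surviving pair scores (p < 0.05);
6. **adaptive LASSO** Cox fit: a 10-fold cross-validated ridge regression
   supplies penalty weights `w_j = 1 / |beta_ridge_j|`, then a 10-fold
   cross-validated weighted LASSO selects the final pairs at the penalty
   minimising the partial-likelihood deviance;
7. the index of sample *s* is `sum_k coef_k * Score_k(s)`; cohorts are
   dichotomised at the median index into low/high risk groups.

Evaluation: Kaplan–Meier curves, the log-rank test, IPCW
cumulative/dynamic time-dependent AUC at 1/3/5 years, Harrell's C-index,
and a covariate-adjusted multivariable Cox model with a calibration table
(the nomogram's computational core).

A seeded synthetic-cohort generator with *planted* gene-pair hazard
effects (`h_s = h0 * exp(sum_k beta_k * Score_k(s))`, exponential event
times, calibrated uniform censoring) makes the whole pipeline testable
without any external download.

## Worked example

```r
library(lactpair)

# simulate a 300-sample cohort whose hazard is driven by 5 planted pairs
pp <- data.frame(gene_a = c(1, 3, 5, 7, 9), gene_b = c(2, 4, 6, 8, 10),
                 beta = c(1, -1, 1, -1, 1))
cohort <- generate_cohort(simulation_config(
  n_genes = 50, n_samples = 300, planted_pairs = pp, seed = 42))

fit <- train_lrgpi(cohort$expression, cohort$clinical,
                   config = pipeline_config(seed = 42))
#> excluded 20 sample(s) with follow-up < 1 months
print(fit)
#> Gene-pair prognostic index fit
#>   50 genes -> 12 prognostic -> 522 pairs -> 192 filtered -> 69 screened -> 11 in signature
#>   log-rank chi2 = 108.567 (p = 2.02e-25); C-index = 0.753
#>   AUC: t12 = 0.810, t36 = 0.882, t60 = 0.885
```

The per-stage funnel mirrors the construction above: 12 of 50 genes pass
the gene screen, 522 candidate pairs are enumerated, 192 survive the 70%
consistency filter, 69 the pair-level Cox screen, and the adaptive LASSO
keeps 11 with nonzero coefficients. The trained index separates the
median-split risk groups (log-rank chi-square 108.6) and discriminates
1/3/5-year outcomes with AUC 0.81–0.89 on the training cohort.

A frozen signature scores new cohorts, and is invariant to per-sample
monotone distortion of their expression values:

```r
validation <- generate_cohort(simulation_config(
  n_genes = 50, n_samples = 300, planted_pairs = pp, seed = 4242))
scores <- score_cohort(validation$expression, fit$signature)
concordance_index(scores, validation$clinical)
#> [1] 0.74292

distorted <- apply_platform_transform(validation$expression,
                                      "monotone_nonlinear", seed = 1)
identical(score_cohort(distorted, fit$signature), scores)
#> [1] TRUE
```

Signatures and reports serialize to JSON (`write_signature`,
`write_report`), matrices and clinical tables to TSV (`write_expression`,
`write_clinical`); all writers are deterministic so re-runs diff clean.

## Scope

The package operates on expression matrices that are already on a
within-sample-comparable scale with consistent gene symbols; it performs
no alias mapping, no batch correction beyond what rank-encoding absorbs,
and no count-level preprocessing. See `vignettes/gene-pair-index.Rmd` for
the methodological details and known limitations.
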