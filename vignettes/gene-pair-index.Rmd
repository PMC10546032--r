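---
title: "Building rank-based gene-pair prognostic indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building rank-based gene-pair prognostic indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactpair)
```

## The model

A gene-pair prognostic index replaces absolute expression with binary
within-sample ordering indicators. For genes $G_i$, $G_j$ measured in
sample $s$,

$$\mathrm{Score}_{ij}(s) = \mathbf{1}\left[x_{i,s} > x_{j,s}\right],$$

and the index is a sparse weighted sum of such indicators,

$$\mathrm{index}(s) = \sum_k \hat\beta_k \,\mathrm{Score}_{k}(s),$$

with coefficients estimated by a two-stage adaptive LASSO under a Cox
proportional hazards model. The crucial property is invariance: any
strictly increasing per-sample transformation of the expression matrix
leaves every indicator — and therefore the index — bit-for-bit unchanged.
This is what lets a signature trained on one platform score a cohort
measured on another without renormalisation, and it is asserted literally
(`identical()`) in the test suite rather than up to tolerance.

The inequality is strict and ties score 0. On continuous data ties have
probability zero; on clipped or quantised microarray values they occur,
and the convention must be pinned for the invariance guarantee to hold
exactly. Ties therefore always fall to 0, never to 0.5 or a random draw.

## Construction stages and their parameters

| Stage | Parameter | Default | Why |
|---|---|---|---|
| Follow-up exclusion | `min_followup_months` | 1 | Samples observed for under a month carry almost no partial-likelihood information and can destabilise the fit; "shorter than" is strict, so exactly 1 month is kept. |
| Gene screen | `gene_screen_alpha` | 0.05 | Univariate Cox Wald p, two-sided, *uncorrected*. |
| Consistency filter | `consistency_threshold` | 0.70 | A pair scoring identically in more than 70% of samples is near-constant: it can split at most 30% of the cohort and mostly encodes the two genes' baseline offset, not patient-level signal. Strictly greater than: a 70/30 split is retained. |
| Pair screen | `pair_screen_alpha` | 0.05 | Same convention as the gene screen, applied to the binary pair score. |
| Adaptive LASSO | `n_folds` | 10 | Cross-validated ridge, then weighted LASSO (below). |
| Stratification | cutoff | median | Ties at the cutoff go to the low-risk group — the conservative direction for the high-risk claim, and deterministic. |

No multiplicity correction is applied in either screen. This is
deliberate: the screens are feature *pre-selection* feeding a penalized
fit that performs the actual selection; an FDR-controlled screen would
change which features the LASSO ever sees and is a different procedure.
Users doing inference on individual pairs should not read screen p-values
as calibrated after selection.

### Pair enumeration and orientation

Candidate pairs put a screened (prognostic) gene first against every
other gene in the candidate universe. When both genes of an unordered
pair are prognostic, the two orientations are redundant — their score
rows are exact complements, hence perfectly collinear, and admitting both
would destabilise any penalized fit. Exactly one orientation is kept: the
one whose first gene has the smaller screen p-value, with lexicographic
order breaking ties. For $|P|$ prognostic genes in a universe of $|G|$,
the count is $|P|\,|G| - |P| - \binom{|P|}{2}$.

### The adaptive LASSO

Stage 1 fits an L2-penalized Cox model over a descending penalty grid,
10-fold cross-validated, and takes the coefficient vector at the penalty
minimising the mean partial-likelihood deviance. Stage 2 converts those
coefficients into per-feature penalty factors

$$w_j = \min\!\left(1/|\hat\beta^{\mathrm{ridge}}_j|,\ 10^6\right)$$

and fits an L1-penalized Cox model with those factors, again selecting
the deviance-minimising penalty (`lambda_min`; the 1-SE rule is exposed
as an option but is not the default, because the construction targets the
minimum deviance, not the sparsest model within noise of it). The cap
$10^6$ exists because ridge coefficients are never exactly zero but can
be small enough to overflow the weight; features hitting the cap are
effectively excluded. Penalized fits run through `glmnet` with a
convergence threshold of $10^{-16}$, tight enough that exchangeable
(duplicated) columns receive coefficients equal to well below test
tolerances.

Binary pair features are **not** standardized before penalization. They
already share the common $\{0,1\}$ scale; standardizing would divide each
by its prevalence-dependent standard deviation, up-weighting exactly the
near-constant pairs the consistency filter exists to suppress. The test
suite pins `standardize = FALSE` as the default rather than re-deriving
it per fit.

Cross-validation folds are stratified on event status and keyed to
*sorted sample ids* under the fold seed, not to row positions: permuting
the columns of the input matrix provably cannot change the fitted
signature (a property test asserts this). Two degenerate candidate sets
are handled explicitly rather than passed to the penalized fitter: zero
candidates yield an empty signature (a legitimate outcome on null data),
and a single candidate receives its unpenalized univariate Cox
coefficient, since penalized selection among one feature is vacuous.

## Survival statistics

Cox models are maximized with Efron tie handling — survival times
recorded at month resolution tie heavily, and Efron is the more accurate
approximation; on tie-free data it coincides with Breslow, which the
tests check. Monotone-likelihood fits (perfect separation, where the
partial likelihood has no finite maximizer) are detected by the iterate
exceeding $|\beta| = 20$ — far beyond any estimable biological log hazard
ratio — and returned as `converged = FALSE` rather than as a silently
huge coefficient. Screens treat non-converged fits as non-informative
(the feature is dropped). Zero-information tables, where every event's
risk set is constant in the covariate, are a distinct degeneracy: the
partial likelihood is flat and the fitter reports a zero or undefined
effect, never a spurious finite one.

The time-dependent AUC is the cumulative-case / dynamic-control
estimator with inverse-probability-of-censoring weights taken from the
Kaplan–Meier estimate of the censoring distribution (cases weighted by
$1/\hat G(T_i^-)$, controls by $1/\hat G(t)$). The choice matters: AUC
estimators for censored data can differ by a few points on the same data,
and no single convention is universal for "1/3/5-year AUC". The
cumulative/dynamic IPCW form is the most common one and has two
properties the tests exploit as oracles: with no censoring it collapses
*exactly* to the plain binary AUC of $\mathbf{1}[T \le t]$ against the
score, and it depends on scores only through ranks. Concordance is
Harrell's C over usable pairs with score ties counting $1/2$; the
"nomogram" deliverable is the covariate-adjusted Cox model's linear
predictor plus a quantile-binned calibration table of predicted (Breslow
baseline) versus Kaplan–Meier observed survival — the chart itself is
presentation, the model is the computation.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the method
assumes, not any particular assay:

- expression is Gaussian on the log2 scale with per-gene location and
  scale (defaults: means Uniform(4, 8), sd 1) — the simplest marginal
  model in which within-sample orderings are non-degenerate with
  probability 1;
- the hazard of sample $s$ is
  $h_s = h_0 \exp\big(\sum_k \beta_k\, \mathbf{1}[x_{a_k,s} > x_{b_k,s}]\big)$
  with $h_0 = 0.02$ events/month, and event times are exponential given
  $h_s$ — proportional hazards holds *by construction*, so Cox recovery
  of the planted $\beta$ is a valid oracle for the generator itself;
- censoring is uniform $(0, u]$ with $u$ calibrated by bisection so the
  realized censoring fraction matches the target (default 30%); the
  bound starts at `max_followup` (120 months) and widens automatically
  when the target demands less censoring than that window can deliver —
  bisection rather than rejection sampling keeps the cohort a pure,
  fast function of the seed;
- genes appearing in a planted pair have their two means equalised, so
  the planted indicator is balanced across samples. An unbalanced
  planted pair would be near-constant, be removed by the consistency
  filter, and make every recovery experiment vacuous; balancing is
  therefore part of the experimental design, not a convenience;
- times are in months throughout, matching the 1-month exclusion rule
  and the 12/36/60-month evaluation horizons.

What the generator does *not* emulate: negative-binomial count noise,
batch structure beyond per-sample monotone distortions, tumor purity,
correlated co-expression modules, or informative censoring. Passing
tests demonstrate that the pipeline recovers planted rank-based signals
under proportional hazards with independent censoring; they do not
certify performance on real cohorts, where effects are weaker,
correlated and possibly non-proportional.

`apply_platform_transform()` provides the distortions used to probe
invariance: per-sample affine maps $a_s x + b_s$ ($a_s > 0$) and strictly
increasing cubics $a_s x^3 + b_s x + c_s$ ($a_s, b_s > 0$, derivative
$3a_s x^2 + b_s > 0$ everywhere).

## Problem sizes and numerical choices

The simulation studies shipped with the package use cohorts of $n = 300$
samples and 50 genes with five planted pair effects of $|\beta| = 1$ at
30% censoring, evaluated over 20 seeded replicates with independent
held-out cohorts of the same design — large enough for stable recovery
statistics while keeping a full replicate set comfortably interactive.
Large-sample consistency checks (planted $\beta$ within $\pm 0.15$) use
$n = 2000$. Null calibration runs 20 replicates of 1000 features each.

Numerical pins worth knowing: glmnet convergence threshold $10^{-16}$;
monotone-likelihood declaration at $|\beta| > 20$; JSON writers emit 10
significant digits with stable key order so repeated runs are
byte-identical (`write_report` omits the timestamp by default for the
same reason); the stratification cutoff is the exact sample median, with
ties to low.

## Known limitations

- Gene symbols must already be consistent between cohorts; no alias
  resolution is attempted.
- Missing expression values cause the affected gene to be dropped before
  pairing (a pair score is undefined on missing data); there is no
  imputation.
- No stratified Cox, time-varying covariates, or competing risks.
- Screens are marginal; a pair prognostic only conditionally on others
  will be missed upstream of the LASSO.
- On null data the `lambda_min` rule admits a handful of noise pairs
  (median support ≤ 5 in the shipped null study); consumers wanting
  sparser-than-deviance-optimal models should switch to the exposed
  `lambda_1se` rule.
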