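---
title: "Methods: metabolite-augmented risk prediction with metabrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolite-augmented risk prediction with metabrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Given a matched case-control sample nested in a prospective cohort - cases of
two cancers, each paired 1:1 with a disease-free control on age, enrollment
date and race/ethnicity - do pre-diagnostic metabolite measurements add
predictive value beyond established demographic, clinical and lifestyle risk
factors? The package implements the full analysis pipeline needed to answer
that question honestly: multi-platform metabolomics preprocessing, two
variable-selection procedures, stability selection over multiply imputed
datasets, Monte-Carlo cross-validated AUC for six joint
selection-plus-prediction procedures, and proportion-of-explained-variation
(PEV) reporting. Because real cohort data of this kind are access-restricted,
a first-class synthetic-cohort generator with known signal structure makes
every stage testable end to end.

## The synthetic cohort

`generate_cohort()` draws cases for two outcomes (A, the larger breast-like
series, default 577; B, the smaller colorectal-like series, default 181) and
a pool of eligible controls, then selects one control per case by optimal
bipartite assignment (Jonker-Volgenant shortest augmenting paths) within
race/ethnicity strata, minimising the tolerance-scaled distance
`|age gap|/2y + |enrollment gap|/2mo` subject to the hard tolerances (2
years, 2 months). Greedy nearest-neighbour matching does not minimise a
total-distance criterion, and an optimal assignment makes the
exhaustive-enumeration oracle test meaningful. The control pool contains one
guaranteed-compatible control per case, so a feasible matching always exists
by construction; the pool size relative to the retained controls is a knob
(`control_pool_factor`, default 1.5) because the eligible-pool size per
stratum is a study-design quantity with no single canonical value.

Risk covariates (BMI, waist circumference, alcohol, folate, calcium, red
meat, energy expenditure, smoking, colonoscopy history, polyp removal, a
Gail-like risk score, current hormone-therapy use) carry their own modest
case-control shifts so that covariate-only prediction is informative (CV-AUC
roughly 0.52-0.64 at the default sizes, depending on the outcome), with direction and order of magnitude taken from typical
cohort summary tables: adiposity and smoking up in cases, screening history
protective for the colorectal-like outcome, the risk score informative for
the breast-like outcome. Missingness is injected completely at random at the
configured per-variable rates (defaults: under 1% for anthropometry and
smoking, 6% for energy expenditure, about 2% for dietary intakes).

Metabolite abundances are lognormal. On the log scale, a sample's value is a
per-feature baseline, plus a between-participant biological deviation
(SD 0.5), plus a within-batch drift curve (a low-order polynomial in run
position, shared across features and scaled by a per-feature sensitivity in
[0.5, 1.5]), plus platform-specific technical noise. The per-platform
technical SDs (0.205, 0.064, 0.029, 0.433 for the LC-MS-, lipidomics-,
NMR- and GC-MS-like platforms) were chosen once so that expected pooled-QC
median CVs are about 20.7%, 6.4%, 2.9% and 45.4% - the precision ordering
these technologies exhibit. Pooled QC rows (one per 9 study rows, i.e. 3 per
27-sample batch) have no biological deviation. Signal features shift the
case mean of one outcome by `effect_size` total log-scale SDs, so the
single-feature oracle AUC has the closed binormal form
`pnorm(effect_size / sqrt(2))`; defaults put 10 such features (0.5 SD,
alternating sign) on the LC-MS-like platform for outcome B and none for
outcome A, reproducing a signal/null contrast between the two outcomes.
Below-detection-limit censoring removes exactly the lowest
`lod_missing_rate` quantile of each feature's study values (lower-quantile
truncation, not random missingness, matching the semantics of a detection
limit); the NMR-like platform has none. Truth annotations (which features
carry signal, and their effects) are emitted in a sidecar table, never in
the analysis-facing matrices.

What the generator does *not* emulate: correlated metabolite blocks,
feature-specific drift shapes, missingness that depends on case status,
non-lognormal marginals, or any spectral-level artefacts. Tests passing on
this generator therefore certify the pipeline's statistical machinery - not
that any particular real dataset satisfies these assumptions.

## Preprocessing

The chain is fixed, in this order, per platform:

1. **Missingness filter.** Features missing in more than 20% of study
   samples are removed; a feature at exactly 20% is kept ("more than 20%"
   read literally). QC rows are excluded from the denominator.
2. **Half-minimum imputation.** Every missing entry becomes half the
   feature's minimum nonzero observed value - the standard deterministic
   stand-in for below-detection-limit censoring. Metabolites are *not*
   re-imputed by the chained equations: censoring is their missingness
   mechanism.
3. **Covariate multiple imputation.** `impute_covariates_mice()` iterates
   per-variable conditional models (predictive mean matching with 5 donors
   for continuous variables, Bayesian-draw logistic regression for binary
   ones) for 10 burn-in sweeps, m = 10 copies by default (m is not dictated
   by theory here; 10 is a conventional choice and is exposed in
   configuration). The case/control label is excluded from every model
   matrix, which we verify by flipping the outcome and asserting
   bit-identical imputations - outcome-ignoring imputation is what licenses
   reusing one imputation across the honest cross-validation below.
4. **Outlier truncation.** Values are clipped to within 3 interquartile
   ranges of the quartiles (type-7 quantiles; the quantile convention is not
   canonical, so the test suite recomputes the clip with an independently
   coded quantile formula). Bounds are computed per variable across all
   samples of an imputed dataset, not per batch. As long as fewer than a
   quarter of values are clipped per side, the quartiles of the output equal
   those of the input, so the step is idempotent.
5. **QC-anchored loess normalisation** (LC-MS- and GC-MS-like platforms
   only, where drift is material). Per batch and feature, a loess curve
   (span 0.75, local quadratic, direct surface so predictions extrapolate
   beyond the QC run-order range) is fit to log QC intensity versus run
   order; all values in the batch are divided by the curve's prediction and
   rescaled by the batch QC median, preserving units. The fit is on the log
   scale because drift is multiplicative. Batches with fewer than 4 QC rows
   fall back to median scaling (ratio of overall to batch QC median,
   computed from the *input* so the transform is idempotent), with the
   affected batches recorded. At the default QC density (3 per batch) the
   fallback is the operative path; the loess path engages when batches are
   longer or QCs denser.

Re-running the chain on its own output is exactly a no-op in the fallback
regime and when QC rows are noiseless (a loess smoother is linear, not a
projection, so with noisy QCs the second pass re-smooths residuals by a
small amount; the test suite pins the exact-no-op regimes). Note also that
because truncation precedes normalisation (following the order the
procedure is usually described in), a re-run after normalisation can clip a
handful of additional tail values; this interaction is inherent to that
ordering.

`qc_median_cv()` summarises platform precision as the median over features
of `100 * SD / mean` across replicate QC rows, excluding non-positive-mean
features.

## The Super Learner

`fit_super_learner()` is a from-scratch stacking ensemble for binary
outcomes. Candidate learners are fit in a V-fold stratified cross-validation
(V = 10 by default, matching the ten-fold convention used for the lasso;
smaller V is used in tests and is configurable); the held-out probability
matrix Z is collected; and the ensemble weight vector solves

    minimise over the simplex:  mean NLL(y, Z w)

with probabilities clipped to [1e-6, 1 - 1e-6]. The minimisation uses a
softmax reparameterisation with BFGS from multiple starts (uniform and each
vertex), and the exact vertices compete as candidate solutions, which
guarantees the ensemble's cross-validated risk never exceeds the best single
learner's. For up to three learners the optimum is verified against a
0.01-step simplex grid search in the test suite. Learners are refit on the
full data for prediction; a learner that fails in any fold is dropped with a
warning.

The default library is elastic-net logistic regression at mixing parameters
{0.25, 0.5, 0.75, 1} (lambda by internal cross-validation), boosted trees at
depths {2, 4} (500 rounds, learning rate 0.1), and a 1000-tree probability
random forest - each tuning point a separate library member. These grids are
declared defaults, not canonical values; tests use lighter members
(fewer trees/rounds, smaller internal folds) to keep runtimes proportionate,
which exercises identical code paths.

Variable importance: absolute standardised coefficients for the elastic net
(sign recorded separately by the reporting stage), impurity decrease for
forests, and split gain for boosted trees (the gradient-boosting analogue of
impurity decrease). Importances are converted per learner to ranks
(1 = most important) with ties broken by stable column order, making each
learner's ranks a permutation and reruns identical.

Screens (`screen_top_univariate()`, `screen_lasso()`) wrap a learner with a
feature-selection rule re-applied inside every training fold, for the
screen-augmented library variant; forced design covariates always survive a
screen.

## Variable selection and stability

Two procedures:

* `lasso_select()`: penalised logistic regression with penalty factor 0 for
  the forced design covariates, lambda by 10-fold cross-validated deviance.
  The default lambda rule is the one-standard-error rule. This is a
  deliberate choice: simulations (run before freezing the tests) showed the
  deviance-minimising lambda selects spurious metabolites in most pure-noise
  datasets and produces ~20% stable false positives in the recovery
  experiment below, while the 1-SE rule returns a clean support in 10/10
  pure-noise runs at essentially no cost in power for 0.5-SD effects. The
  minimising rule remains available (`lambda_rule = "min"`).
* `sl_rank_select()`: the weighted rank of variable j is
  `sum_l w_l * rank_l(j)` with the Super Learner's convex weights; the k =
  20 smallest weighted ranks are selected. Forced covariates do not consume
  the budget (they are design variables, not candidates); ties break by
  column order.

`stability_select()` applies a procedure to each of the m imputed datasets
and flags variables selected in strictly more than 70% of them ("over 70%"
read strictly: 7 of 10 does not qualify). `union_final()` unions the two
procedures' final sets within platform, then unions metabolites across
platforms, reporting covariates as the unique covariates selected anywhere.
Because the m imputations share all metabolite values, the
imputation-to-imputation variability for metabolites comes from the
selection procedure's internal cross-validation; stability filtering
therefore removes variables whose selection depends on the fold draw, not
dataset-level spurious associations - a limitation inherited from the
design.

## Honest performance assessment

`cv_evaluate()` implements the anti-leakage contract: in every Monte-Carlo
replication a fresh stratified partition is drawn (5 folds by default; the
replication count defaults to 100), and the *entire* procedure - selector
then predictor - is refit inside each training fold. Held-out rows never
inform selection, which an in-loop assertion and a recorded audit enforce. A
replication's AUC is the mean of its fold AUCs (pooling out-of-fold scores
across folds is known to bias AUC downward under the null, because fold-
specific calibration offsets corrupt between-fold comparisons). With
multiply imputed data, per-imputation held-out predictions are averaged
within the fold before the AUC (default), or per-imputation AUCs are
averaged (`mi_combine = "rubin"`); both are implemented because the original
combination rule for this statistic is not canonical. The 95% confidence
interval is the normal approximation from the standard error of the
replication AUCs.

`cv_evaluate(null_calibrate = TRUE)` permutes the outcome labels afresh in
each replication. A single fixed permutation would leave a dataset-level
spurious AUC of order 1/sqrt(n) that no number of partitions averages away;
redrawing the permutation per replication makes replicate AUCs iid with mean
exactly one half, so the report's CI is a valid null-calibration check.

The six procedures are: `SL` (Super Learner, all variables),
`SL_screens` (screen-augmented library), `lasso_GLM`, `lasso_SL`,
`SL_GLM`, `SL_SL` (selector x predictor). Sensitivity switches reproduce
the two post-hoc analyses: `exclude_ht` removes current hormone-therapy
users before imputation, and `pooled = TRUE` joins all platforms'
preprocessed features before selection, evaluated with `lasso_GLM` only.

`compute_pev()` reports, per selected variable, the correlation between the
observed binary outcome and out-of-fold logistic predictions from the design
covariates plus that variable (and jointly for the full set); directions are
the coefficient signs of the full multiple logistic regression. Separated
logistic fits fall back to a lightly ridge-penalised fit.

## Numerical choices and degenerate inputs

* Probabilities are clipped at 1e-6 before any log-likelihood.
* The lasso's lambda path stops at 1% of lambda-max. The cross-validated
  lambda (either rule) sits far above that floor on data of this shape, while
  the near-saturated tail of the path is where coordinate descent converges
  slowest, so the bound changes no selections and removes the pathological
  fits.
* Stratified fold assignment deals shuffled class members out cyclically;
  partitions with a one-class fold are redrawn (up to 25 attempts).
* A constant variable is a no-op for truncation; a feature with no nonzero
  observed value is an error for half-minimum imputation (there is no
  anchor); a degenerate outcome is an error everywhere.
* All randomness flows from named integer seeds through
  `withr::with_seed`; child seeds are derived, never taken from the global
  stream, so fixed seeds give byte-identical outputs.

## Problem sizes used by the tests and the acceptance script

The test suite runs the generator at reduced sizes (tens of cases,
10-40 features per platform) chosen to keep the full suite proportionate
while leaving every statistical property measurable: ensemble-weight
validity over 100 random fits; exact agreement of the preprocessing
operations with brute-force recomputations on 50 fixtures; a >= 2x QC-CV
reduction under two-fold injected drift over 5 seeds; null calibration of
all six procedures at n = 300 with 100 label-permuted replications;
a signal/null CV-AUC contrast at 150 cases per outcome and 25 replications;
and stability-selection recovery on the full-size default cohort over 5
seeds. `scripts/acceptance.R` runs the default full-size cohort (758 cases,
758 controls, four platforms) with 12 evaluation replications and m = 5
imputations.

## Known limitations

* Independent features mean the generator cannot probe selection behaviour
  under strong metabolite correlation (where lasso support instability is
  worst).
* Stability over imputations shares one dataset; it is not subsampling
  stability selection and controls only fold-draw variability for complete
  variables.
* The chained-equations implementation covers continuous and binary
  variables (the cohort table's types); unordered factors with missingness
  are not supported.
* PEV on the correlation scale depends on case prevalence in the matched
  sample; values are comparable within a study, not across designs.
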