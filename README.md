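# metabrisk

Do metabolites add cancer-risk prediction beyond established risk factors?

`metabrisk` is an R package for analysts working with matched case-control
metabolomics studies nested in prospective cohorts. It implements the full
pipeline such a study needs: multi-platform metabolomics preprocessing, two
variable-selection procedures, stability selection across multiply imputed
datasets, honest Monte-Carlo cross-validated AUC comparison of six joint
selection-plus-prediction procedures, and proportion-of-explained-variation
(PEV) reporting. Because data of this kind are typically access-restricted,
the package ships a first-class synthetic-cohort generator with a known,
configurable signal structure, so every stage is testable end to end.

## The statistics at the core

**Super Learner.** For candidate learners with held-out probability
predictions collected in a matrix *Z* (V-fold cross-validation, stratified
on the outcome), the ensemble weight vector solves

&nbsp;&nbsp;&nbsp;&nbsp;min<sub>w ∈ Δ</sub> −(1/n) Σ<sub>i</sub> [ y<sub>i</sub> log(Zw)<sub>i</sub> + (1−y<sub>i</sub>) log(1−(Zw)<sub>i</sub>) ]

over the probability simplex Δ (non-negative log-likelihood loss). The
library covers elastic-net logistic regression, boosted trees, and random
forests; each tuning point is a separate member.

**Selection.** (i) Lasso-penalised logistic regression with penalty factor 0
for the design covariates (age, enrollment time, race/ethnicity — forced
into every model), λ by 10-fold cross-validated deviance (1-SE rule by
default); selected = nonzero support. (ii) Super-Learner-weighted ranks:
with per-learner importance ranks r<sub>l</sub>(j) and ensemble weights
w<sub>l</sub>, variable *j*'s weighted rank is Σ<sub>l</sub> w<sub>l</sub>
r<sub>l</sub>(j); the top 20 are selected. A variable is **final** when it
is selected in strictly more than 70% of the multiply imputed datasets;
final sets are unioned over the two procedures, then over platforms.

**Honest CV-AUC.** In each of 100 Monte-Carlo replications a fresh
stratified 5-fold partition is drawn and the *whole* procedure — selection
and prediction — is refit inside every training fold; held-out rows never
inform selection. A replication's AUC is the mean of its fold AUCs
(rank-based, ties counted ½).

**PEV.** The correlation between the observed binary outcome and
out-of-fold logistic predictions from the design covariates plus the
selected variable(s).

## Worked example

```r
library(metabrisk)

# a small matched cohort: two platforms, sparse signal for outcome B only
cfg <- cohort_config(
  n_cases_A = 150, n_cases_B = 150, n_controls = 300,
  platform_sizes = c(lcms = 40, nmr = 12),
  n_signal_features = c(A = 0, B = 10), effect_size = 0.5,
  seed = 71)
cohort <- generate_cohort(cfg)
print(cohort)
#> <synthetic_cohort>
#>   participants: 600 (control=300, case_A=150, case_B=150)
#>   lcms: 40 features, 666 rows (66 QC), 23 batches
#>   nmr: 12 features, 666 rows (66 QC), 23 batches
#>   signal features: 0 (outcome A), 10 (outcome B)

# platform precision from the interspersed pooled QC rows
qc_median_cv(cohort$features$lcms)
#> <qc_summary> median CV 20.3% over 40 features (66 replicates)

# does adding metabolites improve on the risk factors, per outcome?
pp <- preprocess_config(m = 2)
aset <- prepare_analysis_data(cohort, outcome = "B", platform = "lcms",
                              covariate_mode = "metabolites_all",
                              preprocess = pp)
cov_only <- prepare_analysis_data(cohort, outcome = "B",
                                  covariate_mode = "covariates_only",
                                  preprocess = pp)
r_met <- cv_evaluate(aset$datasets[[1]], "lasso_GLM", forced = aset$forced,
                     reps = 25, seed = 19)
r_cov <- cv_evaluate(cov_only$datasets[[1]], "lasso_GLM",
                     forced = cov_only$forced, reps = 25, seed = 19)
print(r_met)
#> <cv_auc_report> lasso_GLM: mean CV-AUC 0.849 (95% CI 0.845-0.852; 25 reps x 5 folds, n = 450)
print(r_cov)
#> <cv_auc_report> lasso_GLM: mean CV-AUC 0.475 (95% CI 0.462-0.487; 25 reps x 5 folds, n = 450)
```

The ten 0.5-SD signal metabolites lift the cross-validated AUC from chance
level (the risk-factor shifts in this small example are too weak for the
conservative lasso to retain at n = 450) to 0.849; for the null outcome A
the same comparison leaves the AUC at chance. `run_study()` executes the full grid (outcomes ×
platforms × covariate modes × all six procedures, plus stability selection,
final unions and PEV), `plot_cv_auc()` draws the procedure comparison, and
`orchestrate()` drives generate → preprocess → evaluate from a single YAML
configuration, emitting TSV reports and a digest manifest.

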