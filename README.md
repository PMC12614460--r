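# salpclinrisk

Preoperative aortic rupture is the dominant lethal mechanism in acute type A
aortic dissection (ATAAD), and it is rare: roughly 6% of patients rupture
before surgery, so any predictive model faces severe class imbalance on top
of messy admission data (missing labs, mixed continuous/binary variables).
`salpclinrisk` implements an imbalance-aware machine-learning pipeline for
this setting — for clinical data scientists who want a fully reproducible,
leakage-guarded reference implementation — together with a synthetic cohort
generator calibrated to the published group-wise summary statistics of a
774-patient ATAAD cohort (47 ruptures), so the entire pipeline can be
exercised end to end without access to patient-level hospital data.

## What is inside

**Synthetic cohort generator.** Published cohort tables report, per outcome
group, the median and interquartile range (P25, P75) of each continuous
variable and exact counts for each binary variable. For each continuous
variable and group the generator fits a two-piece (split) log-normal whose
quantile function is

```
Q(u) = exp( log m + Φ⁻¹(u) · σ_lo )   for u ≤ 1/2
Q(u) = exp( log m + Φ⁻¹(u) · σ_hi )   for u > 1/2
```

with `σ_lo = (log m − log p25)/Φ⁻¹(0.75)` and
`σ_hi = (log p75 − log m)/Φ⁻¹(0.75)`, so all three printed quantiles are
matched exactly and the typical right skew of clinical labs is reproduced.
Binary variables are allocated to their exact per-group counts and shuffled.

**Salp Swarm Algorithm (SSA) optimizer.** A from-scratch population
metaheuristic: leading salps move around the food source `F` (best-so-far
position) by

```
x_j = F_j ± c1 · ( (ub_j − lb_j) c2 + lb_j ),    c1 = 2 exp( −(4 t / T)² )
```

with `c2, c3 ~ U(0,1)` drawn per dimension (the sign follows `c3 < 0.5`),
while followers take the midpoint of themselves and their predecessor in the
chain. `c1` decays from 2 to ~2.25·10⁻⁷, shifting exploration to
exploitation.

**SSA-tuned models.** Random forest (4 integer hyperparameters:
`n_estimators ∈ [50,500]`, `max_depth ∈ [3,30]`, `min_samples_split ∈
[2,20]`, `min_samples_leaf ∈ [1,10]`) and XGBoost (5 dimensions, including
continuous `learning_rate ∈ [0.01,0.3]` and `gamma ∈ [0,1]`), each tuned by
minimizing `Fitness = 1 − (1/K) Σ Accuracy_k` under stratified 5-fold
cross-validation with fold-internal SMOTE.

**Leakage-guarded preprocessing.** Stratified 64/16/20 split by
largest-remainder allocation (774 → 495/124/155), chained-equation
imputation per partition, univariate screening (Shapiro-Wilk-gated t /
Mann-Whitney tests; chi-square with Fisher fallback on sparse cells),
SMOTE, and train-fitted standardization — with an auditable assertion that
no train-fitted stage ever reads a test row.

**Evaluation and explanation.** Confusion matrices, accuracy / precision /
recall / specificity / F1, tie-aware ROC-AUC and PR-AUC, calibration curves,
decision-curve net benefit `TP/n − (FP/n)·p_t/(1−p_t)`, threshold sweeps,
and exactly additive Shapley feature attributions with global importance
ranking.

## Worked example

```r
library(salpclinrisk)
library(dplyr)

cohort <- generate_cohort(seed = 1)
cohort |>
  group_by(rupture) |>
  summarise(n = n(), egfr = median(egfr), wbc = median(wbc))
#> # A tibble: 2 × 4
#>   rupture     n  egfr   wbc
#>     <int> <int> <dbl> <dbl>
#> 1       0   727  82.4  12.6
#> 2       1    47  52.9  15.1
```

The 727 non-rupture and 47 rupture rows reproduce the published group
medians (eGFR 82.38 vs 52.52 mL/min/1.73m², WBC 12.87 vs 15.44 ×10⁹/L) up
to sampling noise. A full run — here with a reduced swarm budget so it
finishes in seconds — generates, splits (495/124/155), imputes, screens,
rebalances, tunes, evaluates on the untouched test partition and explains:

```r
run <- run_pipeline(pipeline_config(seed = 1, n_salps = 6, n_iter = 8,
                                    families = "random_forest"))
run$metrics |> select(model, accuracy, precision, recall, f1, roc_auc)
#> # A tibble: 9 × 6
#>   model               accuracy precision recall    f1 roc_auc
#> 1 ssa_random_forest      0.987     0.818  1     0.9     0.995
#> 2 random_forest          0.994     0.9    1     0.947   0.996
#> 3 xgboost                0.981     0.75   1     0.857   0.995
#> 4 logistic_regression    0.981     0.8    0.889 0.842   0.937
#> ...

head(run$attributions$ranking, 5)
#> # A tibble: 5 × 2
#>   feature mean_abs_attribution
#> 1 ast                   0.0358
#> 2 map                   0.0311
#> 3 sbp                   0.0238
#> 4 egfr                  0.0233
#> 5 obesity               0.0224
```

On the 155-row synthetic test set the tuned forest finds all 9 rupture
cases (recall 1.0) with 2 false alarms (precision 0.818); the attribution
ranking recovers hemodynamic and renal variables as leading predictors, as
expected from the generative group contrasts. Note that the synthetic
cohort is easier than real hospital data (independent variables, clean
group separation), so absolute metrics here characterize the pipeline, not
clinical performance. `autoplot()` methods render the convergence trace,
calibration, decision curves and attribution summaries; `tidy()` /
`glance()` return broom-style tables.

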