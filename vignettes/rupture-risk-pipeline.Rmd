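---
title: "Methods: a salp-swarm-optimized pipeline for preoperative rupture risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a salp-swarm-optimized pipeline for preoperative rupture risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salpclinrisk)
```

## The problem

Acute type A aortic dissection (ATAAD) is a surgical emergency; a minority
of patients — about 6% — suffer aortic rupture before the operation, and
identifying them drives triage. Statistically this is a rare-event binary
classification problem on mixed-type admission data: ~20 continuous
variables (vitals, blood gas, hematology, renal and hepatic labs) and ~13
binary history/symptom variables, with partly missing laboratory values.
`salpclinrisk` implements the whole workflow — synthetic cohort generation,
leakage-guarded preprocessing, metaheuristic hyperparameter tuning,
evaluation and attribution — as composable, tibble-first functions.

## The synthetic cohort generator

Patient-level ATAAD data are not publicly deposited; what is published are
group-wise summaries: per outcome group, median (P25–P75) for continuous
variables and count (%) for binary ones, for 727 non-rupture and 47 rupture
patients. `default_cohort_specs()` transcribes those summaries; `generate_cohort()`
turns them into a cohort.

**Continuous sampling law.** Three quantiles per group are all the
information available. We considered a log-normal fitted to (P25, P75) with
a multiplicative shift onto the printed median; that matches the median
exactly but displaces P25/P75 by the ratio of the median to the geometric
mean of the quartiles — for strongly skewed variables (total cholesterol's
non-rupture triple is 0.51/3.35/4.55) the displacement exceeds 100%.
Instead we use a **two-piece (split) log-normal**: each half of the
distribution is a log-normal half with its own log-scale spread,
`σ_lo = (log m − log p25)/z₀.₇₅` below the median and
`σ_hi = (log p75 − log m)/z₀.₇₅` above it. All three printed quantiles are
matched *exactly* by construction, support stays positive, and
`σ_hi > σ_lo` produces the right skew typical of labs. Variables whose
printed quantiles are not all positive fall back to a two-piece normal on
the raw scale (none of the default variables need it). Sampling goes
through the closed-form quantile function, which also makes the optional
Gaussian-copula rank-correlation path exact.

**Binary variables** are allocated to their printed per-group counts
exactly — 575/727 and 30/47 males, for example — then permuted within
group, so prevalences match the source exactly rather than in expectation.

**Correlation.** The default is independence between variables: the source
publishes no covariance information, and inventing one would be
unfalsifiable. A Gaussian copula can be supplied through
`generate_cohort(correlation = )` when a correlation structure is wanted.

**Missingness.** The source states only that laboratory missingness is
below 30% per variable. The default specifications set 8%
missing-completely-at-random on every laboratory variable and 0 elsewhere —
a mid-range, realistic EHR rate that exercises the imputation stage without
dominating it. `inject_missingness()` masks exactly `round(rate · n)` cells
per variable and never touches the outcome.

**What the generator does not emulate.** Real admission data have
correlated labs, informative (not MCAR) missingness, measurement error, and
overlap between groups beyond what independent quantile-matched marginals
produce. Because each variable separates the groups exactly as strongly as
its printed quantiles imply, and variables are independent, the synthetic
classification task is *easier* than the clinical one. Passing tests on
this cohort therefore validate the pipeline's mechanics (calibration,
leakage hygiene, optimizer behavior, metric identities), not clinical
performance.

## Preprocessing

- **Split.** `split_cohort()` uses largest-remainder allocation of
  `n · (0.64, 0.16, 0.20)` within each outcome class, which yields exactly
  495/124/155 from 774 rows and keeps each partition's event prevalence
  within one case of the global 6.1%.
- **Imputation.** `impute_chained()` is chained-equation imputation
  returning a single completed dataset: per incomplete column, iterated
  linear regression (continuous, with residual-scale noise) or logistic
  regression (binary, with a Bernoulli draw) on all other columns, 10
  cycles by default. A single completed dataset (rather than a pooled
  multiple-imputation analysis) is the right target here because one model
  is fitted downstream, not an inferential estimate. Each partition is
  imputed separately so no cross-partition information flows.
- **Screening.** `screen_features()` mirrors standard clinical univariate
  practice: Shapiro-Wilk per group gates t-test vs Mann-Whitney for
  continuous variables; chi-square switches to Fisher's exact test when any
  expected cell count is below 5; selection at p < 0.05. The source
  analysis ultimately fed nine variables to its models while many more pass
  p < 0.05; both readings are supported, so the literal filter is the
  default and `top_k = 9` reproduces the nine-variable reading.
- **SMOTE.** `apply_smote()` oversamples the minority class to parity using
  convex combinations `x + u(x_nn − x)` between a minority row and one of
  its k = 5 nearest minority neighbors (the conventional default). Binary
  features take the nearer parent's value (interpolation thresholded at
  0.5).
- **Standardization.** Centers and scales are fitted on the training
  partition only and applied everywhere; `audit_leakage()` asserts that
  screening, scaling and SMOTE consumed training rows only.

## The salp swarm optimizer

`ssa_optimize()` minimizes a black-box fitness over a bounded mixed
integer/continuous box. Leading salps are redrawn around the food source
(the best-so-far position) with per-dimension steps
`±c1·((ub−lb)c2 + lb)`, where `c1 = 2·exp(−(4t/T)²)` decays from 2 to
~2.25·10⁻⁷ over the horizon; followers take midpoints along the chain,
swept sequentially (a simultaneous variant is available). Positions are
clamped to the box; the food source is updated after each full population
evaluation and retains the best-so-far (elitism), so the convergence trace
is non-increasing by construction.

**Leader count.** The algorithm's reference implementation updates the
leading *half* of the population around the food source, and with a single
leader the chain occasionally stalls at ~10⁻³ on a 2-D sphere benchmark
(one seed in twenty in our checks) because only one informative sample is
drawn per iteration once the followers collapse onto the chain. The default
is therefore `n_leaders = ceiling(n_salps/2)`; `n_leaders = 1` gives the
strict single-leader chain for comparison.

**Budgets.** The source does not print its population size or iteration
count. Defaults are 20 salps × 50 iterations, comfortably past the point
where convergence traces flatten on these 4–5-dimensional spaces; both are
configurable, and the test suite uses reduced budgets (3–6 salps, 2–8
iterations) chosen so the full suite runs in a few minutes while still
exercising every code path.

## Tuning, fitness and the model zoo

The tuned search spaces are the published ones: four integer dimensions for
the random forest (`n_estimators` 50–500, `max_depth` 3–30,
`min_samples_split` 2–20, `min_samples_leaf` 1–10; mapped onto ranger's
`num.trees`, `max.depth`, `min.node.size`, `min.bucket`) and five for
XGBoost (`n_estimators` 50–500, `max_depth` 3–15, `learning_rate`
0.01–0.3, `gamma` 0–1, `min_child_weight` 1–10). Integer dimensions decode
by rounding half away from zero, then clamping.

The fitness is `1 − mean(Accuracy_k)` under stratified 5-fold
cross-validation, accuracy taken at threshold 0.5. SMOTE is applied
*inside* each fold to the fold-training part only — the only placement that
keeps fold accuracies leakage-free; `cv_fitness(smote = FALSE)` gives the
laxer reading. The identity `fitness + mean(fold accuracy) = 1` holds
exactly. An optional warm start initializes the first leader at a supplied
assignment (e.g. library defaults), which together with elitism guarantees
the tuned fitness never exceeds the default's on the same folds and seed.

`baseline_zoo()` fits eight families at library defaults — random forest,
XGBoost, logistic regression, SVM (Platt-calibrated), k-NN, CART, a
single-hidden-layer perceptron and Gaussian naive Bayes. Eight is the union
of the families the source lists and the families it tabulates, which
disagree; fitting the union reports everything.

## Evaluation conventions

- ROC curves group tied scores into single threshold steps; the trapezoidal
  area then equals the Mann-Whitney U statistic divided by `n₁n₀`, which the
  tests verify exhaustively on small instances.
- PR-AUC integrates precision over recall across unique thresholds; for a
  random scorer it converges to the prevalence.
- Metrics with empty denominators (precision with no predicted positives)
  are reported as `NA`, never coerced to 0.
- Decision curves use net benefit `TP/n − (FP/n)·p_t/(1−p_t)` with
  treat-all and treat-none references; treat-all crosses zero exactly at
  the prevalence.
- Calibration bins are equal-width on [0, 1]; empty bins are omitted.
- The default operating threshold for point metrics is 0.5; the threshold
  sweep exposes alternatives.

## Feature attributions

`shapley_values()` computes interventional Shapley values of the predicted
probability against a background sample (default: a seed-fixed 100-row
training subsample in the pipeline). With ≤ 12 features the full coalition
lattice is enumerated — exact Shapley values; above that, a
permutation-sampling estimator (default 32 permutations) is used. Both are
*exactly* additive: `base + Σ attributions = prediction` per sample, by the
efficiency property in the exact case and because every sampled permutation
telescopes from the empty to the full coalition in the sampled case. Global
importance is the mean absolute attribution, descending; `tidy()` and
`autoplot()` expose long-format values and a summary plot. Tree-specific
path-dependent attribution algorithms exist but change the conditioning
semantics between model families; using one interventional estimator
everywhere keeps rankings comparable across the zoo.

## Determinism and degenerate inputs

Every stochastic step (generation, splitting, imputation noise, SMOTE,
fold assignment, swarm initialization, model seeds, background sampling)
derives from a single integer seed, and model backends run single-threaded,
so identical configuration and seed reproduce byte-identical CSV/JSON
reports. Degenerate inputs are handled explicitly: constant columns screen
out with p = 1 and a warning; zero-variance columns scale by 1 with a
warning; an already-balanced table passes SMOTE unchanged; a fold whose
training part is single-class raises an error naming the fold; fitness
errors abort with the iteration and position attached.

## Known limitations

- The generator's independence default and exact quantile matching make the
  synthetic task cleanly separable; absolute performance numbers on it do
  not transfer to hospital data.
- Missingness is MCAR only; informative missingness would require
  assumptions the source does not support.
- The chained imputation returns one completed dataset; Rubin-style pooled
  inference is out of scope.
- Confidence intervals for AUCs (DeLong, bootstrap) are not provided.
- The published real-data performance cannot be reproduced or audited here
  because the underlying cohort is not deposited; this package validates
  the method, not the clinical claims.
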