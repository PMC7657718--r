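# journeydrop

Dropout (attrition) prediction from user-journey data in digital
health interventions, for intervention researchers and biostatistics
teams who hold raw touchpoint logs — self-reported diary and
questionnaire values plus system events such as log-ins, automated
emails and triggers — and want a tested, reproducible pipeline from
those logs to cross-validated dropout predictions with per-feature
explanations.

## What it computes

Given a long-format log of touchpoints `(user, timestamp, variable,
value, source)` for a gated multi-core program (the motivating case:
7 sequential cores, each released 7 days after the previous core's
completion), the pipeline:

1. bins touchpoints into half-open calendar windows
   `[o + iw, o + (i+1)w)` and aggregates within windows (numeric →
   mean, categorical → mode, events → count), carrying questionnaire
   values forward (LOCF) and dropping single-level categoricals;
2. engineers rolling-window aggregates (sum, mean, min, max, sample
   SD over *w* consecutive observations), optional interaction
   products, and a protected catalog of theory-driven features
   (daily login/email/trigger indicators, days since last contact,
   per-core completion latencies and their running mean,
   clock-difference features, threshold and trend flags);
3. collapses each user to one row by per-variable Sum / Last / Mean /
   Mode rules and attaches the label *y* = 1 if the user never
   completed the final core;
4. deletes features whose missing fraction exceeds a threshold
   τ ∈ {0.05, 0.10, 0.15, 0.20} (protected features exempt) and
   imputes the rest by median/mode or mixed-type KNN (k = 5, Gower-style
   distance);
5. fits L1/L2-regularised logistic regression, SVMs and
   gradient-boosted trees with grid-searched hyperparameters under
   stratified 10-fold cross-validation, reporting AUC (Mann–Whitney
   pair statistic with tie half-credit) and precision–recall area
   (chance level = prevalence) on pooled out-of-fold scores, for one
   analysis per core *c* — restricted to users who completed core *c*
   and to their data up to that completion date;
6. attributes predictions to features with interventional Shapley
   values φ (exact coalition enumeration up to 12 features, otherwise
   permutation sampling; local accuracy Σφᵢ + base = score holds
   exactly in both modes) and ranks features by mean |φ|.

Because the motivating trial's data are not publicly deposited, the
package ships a seeded cohort simulator (`simulate_cohort()`)
reproducing the *structure* the pipeline assumes — gated cores, daily
diaries, system events, and a dropout hazard
`plogis(c0 + 0.3c − b_drop·η + b_lat·L)` driven by latent engagement
η and completion latency L — with the baseline hazard calibrated by
bisection to a target dropout rate (default 39.7%, the complement of
a 60.3% completion rate). Null (`b_drop = b_lat = 0`) and signal
presets support chance-level and signal-recovery testing.

## Worked example

```r
library(journeydrop)

p   <- scenario_params("shuti_like", seed = 1)   # 151 users, ~40% dropout
sim <- simulate_cohort(p)
round(mean(sim$labels$y), 3)
#> [1] 0.437

cfg <- default_config(
  model = list(kind = "logreg_l1",
               grid = lapply(c(0.005, 0.01, 0.02, 0.05),
                             function(l) list(lambda = l)),
               tune = TRUE),
  missingness = list(threshold = 0.15, imputation = "knn", knn_k = 5),
  cv = list(k_folds = 10, stratified = TRUE, seed = 1),
  attribution = list(enabled = TRUE, top_k = 5, mode = "sampled",
                     n_perm = 20, background_n = 25, explain_n = 60,
                     seed = 1))
res <- run_core_analyses(sim$log, sim$labels, cfg)
res$summary
#>     core     n n_dropout       auc    pr_auc pr_baseline best_setting
#> 1:     0   150        65 0.7627149 0.7241970   0.4333333  lambda=0.05
#> 2:     1   143        58 0.7350913 0.7129767   0.4055944  lambda=0.05
#> 3:     2   128        43 0.7206566 0.5662181   0.3359375  lambda=0.02
#> 4:     3   118        33 0.7925134 0.6367383   0.2796610  lambda=0.05
#> 5:     4   105        20 0.7364706 0.4235438   0.1904762  lambda=0.05
#> 6:     5    96        11 0.7572193 0.3046757   0.1145833  lambda=0.05
```

One analysis per core 0–5: `n` is the cohort still eligible at that
core (declining as users drop), `auc` the pooled out-of-fold AUC for
predicting eventual dropout from data available at that point, and
`pr_baseline` the prevalence a chance-level precision–recall area
would sit at. Mean AUC across the six analyses here is 0.751. The
per-analysis Shapley ranking shows *which* behaviour carries the
prediction, e.g. for the core-1 analysis:

```r
res$results$core_1$attribution$ranking[1:5]
#>             feature mean_abs_phi
#> 1:    days_no_diary  0.672331279
#> 2:    nap_day_count  0.071927517
#> 3: sleep_duration_h  0.037105184
#> 4:              age  0.025358158
#> 5:         waso_min  0.009722072
```

A thin CLI (`inst/cli/journeydrop`) wraps the same functions:
`journeydrop simulate`, `journeydrop transform`, `journeydrop
run-all`, exchanging plain CSV/JSON.

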