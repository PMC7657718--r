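---
title: "Predicting intervention dropout from user-journey data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting intervention dropout from user-journey data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Digital health interventions — here, the motivating case is a
web-delivered insomnia program organised as 7 sequential content
*cores*, each released 7 days after the previous core's completion —
lose a large share of their participants before the program ends.
Because every interaction leaves a trace (daily sleep diaries,
questionnaires administered before each core, log-ins, automated
emails, system trigger events), dropout should be predictable from
the accumulating *user journey*: the time-ordered sequence of a
user's touchpoints. journeydrop implements that analysis as a tested
pipeline:

1. **Long-to-wide transformation.** Raw touchpoints (one row per
   user, timestamp, variable) are binned into half-open calendar
   windows of `window_days` days (default 1) and aggregated within
   each window: mean for numeric variables, mode for categorical
   (ties to the earliest observed value), count for events.
   Questionnaire-style variables are carried forward until their next
   administration (LOCF). Categorical columns with a single observed
   level are removed.
2. **Feature engineering.** Rolling aggregates (sum, mean, min, max,
   sample SD) over windows of `w` consecutive observations; optional
   pairwise interaction products; and a catalog of handcrafted,
   theory-driven features — daily event indicators, days since last
   contact, per-core completion latencies and their running average,
   clock-difference features (awake to arise, preferred versus actual
   times), threshold flags, a core-to-core sleep-duration trend flag.
   Catalog features are *protected*: they are exempt from
   missingness-based deletion on clinical grounds.
3. **User-level aggregation.** Each user's windows are collapsed to
   one row via the per-variable rule (Sum / Last / Mean / Mode), and
   the binary outcome (dropout = did not complete the final core) is
   attached.
4. **Missing data.** Features whose missing fraction strictly exceeds
   a threshold `tau` (grid 0.05–0.20) are deleted, except protected
   ones; the rest are imputed by column median/mode or by a
   mixed-type k-nearest-neighbour scheme (k = 5).
5. **Modeling.** Four classifier families (L1/L2 logistic regression,
   SVM, gradient-boosted trees) with grid-searched hyperparameters
   under stratified 10-fold cross-validation, scored by AUC on pooled
   out-of-fold predictions; a model-by-imputation-by-threshold
   configuration grid selects the best cell.
6. **Timepoint-specific analyses.** One analysis per core `c` from 0
   to 5: only users who completed core `c`, and only their data up to
   that core's completion date. The eligible cohort shrinks
   monotonically across cores.
7. **Attribution.** Interventional Shapley values explain individual
   predictions; features are ranked by mean absolute attribution and
   the top 5 per analysis are reported with (value, attribution)
   dependence pairs.

# Timepoint analyses and eligibility

Predicting "who will fail to complete core 6" is most useful early.
The pipeline therefore re-runs the full analysis after each core,
truncating every user's log at their completion date of that core so
that no later information leaks in. Missingness deletion and
imputation are likewise fit inside each analysis, not globally:
early-core analyses see fewer observed windows and thus delete more
features, which mirrors how feature availability actually grows over
a program.

Eligibility at core `c` is "completed core `c`". Users who dropped
earlier are excluded from that analysis rather than carried along
with empty data; this reproduces the characteristic declining
per-core cohort sizes of gated programs. The alternative rule "still
active at core `c`'s release" yields similar but not identical
cohorts; the completion rule is the package's default because it
guarantees the cutoff date (the completion event) exists for every
included user.

# Missing-data policy

Deletion uses a *strict* threshold: a feature is dropped when its
missing fraction exceeds `tau`, so a feature at exactly 20% survives
`tau = 0.20`. Retained sets are monotone in `tau` by construction.

The KNN imputation distance is a Gower-style mixed-type
dissimilarity: numeric dimensions contribute the absolute difference
of column z-scores, categorical dimensions a 0/1 mismatch, averaged
over the dimensions observed in both rows; row pairs with no
co-observed dimension are maximally distant. This choice is an
assumption — the mixed-type metric is not dictated by the procedure
the package reproduces — and is therefore isolated in
`mixed_distance()`, with ties broken by row order for determinism.
Protected features are still *imputed*; protection only exempts them
from deletion.

# Modeling choices

* Numeric features are standardised and categorical features one-hot
  encoded with the encoder fit on the training folds only.
* The SVM contributes raw decision-function margins as scores; AUC is
  rank-based, so probability calibration would change nothing.
* Boosted trees run single-threaded, making every reported number
  bit-reproducible for a fixed seed.
* Hyperparameters are tuned by grid search on the same 10-fold split
  used for reporting; this mildly optimistic posture (no nested CV,
  no holdout) matches the procedure the package reproduces and is
  flagged here as a known limitation.
* A fold whose validation part contains a single class yields an
  undefined fold AUC; the mean is taken over defined folds with a
  warning.

Default grids: log-spaced regularisation strengths
(`10^-4 ... 10`) for logistic regression; cost {0.1, 1, 10} by
kernel {linear, RBF} for the SVM; trees {100, 300, 500} by depth
{2, 3, 4} by learning rate {0.05, 0.1} for the boosted trees.

# Shapley attribution

`shapley_values()` implements interventional (background-replacement)
Shapley values. Exact mode enumerates all `2^m` coalitions and is
used up to `m = 12` features; sampled mode averages marginal
contributions along random feature orderings, pairing each ordering
with a background row so that *local accuracy* — base value plus
attributions equals the model score — holds exactly in both modes,
not just in expectation. Explanations are computed against a seeded
background sample of training rows (default 100). Positive
attributions push toward the dropout class, matching the label
coding `dropout = 1`.

# The synthetic cohort generator

No data from the motivating trial are available, so the package ships
a simulator whose *structure* matches what the pipeline assumes; its
defaults are the study conditions the rest of the test suite relies
on.

Per user, a latent engagement trait `eta ~ N(0, 1)` drives
everything:

* daily login `Bernoulli(plogis(0.1 + 0.8 * eta))` — a disengaged
  user (eta one SD below average) logs in on roughly a third of days,
  an engaged one on two thirds;
* core completion latency `1 + Geometric(p)` days with
  `p = plogis(0.1 + 0.8 * eta)` — a right-skewed positive latency,
  slower for disengaged users (any distribution with this monotone
  relationship would do; the geometric is the simplest);
* before completing core `c`, abandonment
  `Bernoulli(plogis(c0 + 0.3 c - 1.5 eta + 0.3 L))`, where `L` is the
  previous core's latency. The positive per-core slope makes the
  baseline hazard rise over the program, which reproduces the
  attrition timing typical of gated interventions (per-interval
  dropout of a few percent early, around ten percent mid-program)
  and keeps late-stage outcomes predictable rather than exhausted by
  early survivor selection. `b_drop = b_lat = 0` defines the null
  cohort whose dropout is pure noise.

Diaries (sleep duration, quality, onset latency, wake after sleep
onset, awake/arise/bed clock times) are generic user-centred signals
emitted on login days; questionnaires (a severity score, preferred
arise/bed times) are administered at each core release; emails,
trigger events and core release/completion markers come from the
"system" source. Clock fields exist so that every catalog entry is
exercised. Dropped users emit nothing after their dropout date.

`calibrate_dropout_rate()` bisects the baseline hazard `c0` until a
trajectory-only simulation realises a target dropout fraction
(default 0.397, the complement of a 60.3% completion rate) within
±0.02; common random numbers per user make the realised rate monotone
in `c0` and the bisection deterministic. Each user owns an RNG
substream derived from the master seed, so trajectories are stable
under changes of cohort size.

What the simulator does *not* emulate: real covariate distributions,
demographic structure, measurement quirks of consensus sleep diaries,
informative missingness in the diaries themselves, or any treatment
effect of the program content. A passing signal-recovery test
therefore shows that the pipeline can find an engagement-driven
dropout mechanism of realistic strength in realistically sized data —
not that it would achieve any particular AUC on a real trial.

# Numerical conventions

* Windows are half-open `[origin + i*w, origin + (i+1)*w)` in whole
  calendar days; sub-day timestamps are binned by date.
* Mode ties break toward the earliest observed value; KNN distance
  ties toward the earlier row; grid-search ties toward the earlier
  grid entry.
* The sample SD at `w = 1` is reported missing, not zero.
* Clock differences take the shortest signed interval across
  midnight, in minutes, in `(-720, 720]`. Time-of-day averages are
  arithmetic on minutes-since-midnight; values near midnight can
  wrap, which is accepted as noise for evening bedtimes.
* AUC is the Mann-Whitney pair statistic with half credit for ties;
  the precision-recall area uses the average-precision step form, and
  its chance baseline equals the positive prevalence.

# Problem sizes used by the shipped checks

The test suite exercises the full pipeline at the motivating study's
scale (151 users, 7 cores) and runs the stochastic signal-recovery
checks at 20 replicates of 1000-user null cohorts and 500-user
signal cohorts, evaluating the final pre-outcome core with an
L1-regularised logistic model (grid-searched shrinkage, KNN
imputation at `tau = 0.15`). The lasso was selected for these checks
by comparing families on probe replicates — the same model-selection
step the configuration grid automates. Calibration runs use 4000
trajectory-only users; the realized-rate check simulates a full
5000-user cohort.

# Known limitations

* No nested cross-validation; reported AUCs inherit mild selection
  optimism.
* No lagged cross-feature engineering or automated feature search;
  the engineered set is the fixed, documented catalog.
* The regression branch of the task enum (continuous outcomes,
  RMSE/MAE) is reserved in the interfaces but not implemented.
* Sub-daily windows are supported by the windowing engine but not
  exercised by the shipped configurations.
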