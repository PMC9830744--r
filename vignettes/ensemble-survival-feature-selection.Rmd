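---
title: "Ensemble feature selection for censored survival data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble feature selection for censored survival data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survefs)
```

## The problem

In clinical cohorts followed for the onset of a disease, most participants
never experience the event during the study — censoring rates above 90% are
common in population-based dementia cohorts — while the candidate predictor
set mixes continuous measurements, yes/no indicators and small categorical
codes, often with one to two hundred features for under a thousand
participants. Feature selection in this regime is notoriously *unstable*:
rerunning the same selector on a slightly perturbed training set returns a
visibly different subset, which undermines any biological reading of the
selected features.

`survefs` implements the homogeneous-ensemble remedy: run one base selector
on many bootstrap resamples of the training data, combine the resulting
rankings with a rank/score aggregator, and cut the aggregated ranking with
either a fixed or a data-driven threshold. A repeated, event-stratified
cross-validation harness quantifies each configuration by two numbers on
$[0,1]$ — the mean held-out concordance index of a ridge Cox model refitted
on the selected features, and the relative weighted consistency of the
selected subsets — and by their Euclidean distance from the origin.

## The pipeline, stage by stage

For each of the $K \times R$ training folds (default $5 \times 5$):

1. **Impute** missing values with a hook fitted on training rows only
   (default: median/mode; any `fit`/`apply` pair, e.g. a chained-equations
   wrapper, can be substituted).
2. **Normalise** continuous features to mean 0, sample standard deviation 1
   (denominator $m-1$), again with training-row parameters; boolean and
   categorical columns pass through. Zero-variance features map to zero and
   are flagged rather than erroring.
3. **Bootstrap** the training fold $B$ times (default 50). When probe
   thresholding is enabled, each resample is augmented with one permutation
   probe per continuous and categorical feature — a permuted copy that keeps
   the marginal distribution but severs any link to the outcome. Probes from
   boolean features are not generated: a permuted binary vector leaves many
   positions unchanged and can score spuriously well.
4. **Select** with the base selector on each resample. Filters return a
   score per feature; sparse selectors return a subset with positive scores.
5. **Aggregate** the $B$ ranked lists (see below).
6. **Threshold** the aggregated ranking, strip probes, and fall back to all
   features (with a logged warning) if the selection degenerates to empty,
   so a risk model can always be fitted.
7. **Evaluate**: fit a ridge Cox model on the selected features and score
   its held-out concordance.

Every random stage derives its seed deterministically from the master seed
via a splitmix-style hash of the (repeat, fold, bootstrap) path, so a whole
experiment — or any single bootstrap — is exactly reproducible.

## Aggregators

Given $B$ ranked lists over a universe of $p$ features (plus probes),
normalised rank is position divided by $p$; features missing from a sparse
list count as worst (normalised rank 1, score 0), which makes every
aggregator total.

- **Mean rank (MR)** — the Borda count: ascending mean of positions.
- **Mean weight (MW)** — descending mean of importance scores.
- **Robust rank aggregation (RRA)** — for each feature, compare its sorted
  normalised ranks $r_{(1)} \le \dots \le r_{(n)}$ with the order statistics
  of $n$ uniforms: $\beta_{k,n}(x) = \sum_{l=k}^{n} \binom{n}{l} x^l
  (1-x)^{n-l}$ is the null probability that the $k$-th smallest rank is at
  most $x$, and the feature's score is $\rho = \min_k \beta_{k,n}(r_{(k)})$,
  computed through the binomial survival function for numerical stability.
  Features with $\rho$ below the chosen level (0.05–0.25 presets) are
  selected; RRA therefore aggregates *and* thresholds. $\rho$ is reported
  uncorrected by default; a Bonferroni factor of $n$ is available behind
  `correct = TRUE`. Note that $\rho$ is *not* a calibrated p-value: the
  minimum over $k$ is anti-conservative, and over sparse partial lists
  dramatically so — being listed at all is already a top-rank event under
  the uniform null, so any feature selected in roughly half the bootstraps
  gets a tiny $\rho$ regardless of the level chosen (see "When do ensembles
  help?").
- **Threshold Algorithm (TA)** — top-$k$ by total score with early
  stopping: walk the score-sorted lists depth by depth, complete newly seen
  features by random access, and stop once the current best $k$ aggregates
  all reach the depth threshold (the sum of the current depth's scores).
  Equivalent to brute-force top-$k$ by summed score; ties at the boundary
  keep the lexicographically smaller name.
- **MedRank (MA)** — sequential access outputting a feature once it has
  appeared in more than a fraction (default 0.2, the weak-signal variant of
  the classical majority rule) of the lists, stopping early at $k$.

For TA and MA, $k$ defaults to the round-half-up mean of the per-list
subset sizes; pure filters have no natural subset length, so $k$ falls back
to a quarter of the original features, with a warning.

## Thresholds

- `fixed:<f>` — top $\mathrm{round}(f \cdot p)$ original features
  ($f \in \{0.10, 0.25, 0.33\}$ conventionally).
- `q75` — features whose aggregated score strictly exceeds the
  linear-interpolation 75th percentile of the original-feature scores.
- `kde` — one-dimensional clustering of the scores by Gaussian kernel
  density estimation with the robust Silverman bandwidth
  $0.9 \min(s, \mathrm{IQR}/1.34)\, m^{-1/5}$, evaluated on a 512-point
  grid over $[\min - 3h, \max + 3h]$, extrema located by sign changes of
  first differences. Assuming most features are irrelevant, the
  highest-density peak is the irrelevant cluster; the cut is the first
  local minimum above it. A unimodal estimate triggers bandwidth shrinkage
  by 0.75, up to 10 attempts, after which no thresholding is performed.
  Two caveats a user should know: the method needs a genuinely large
  irrelevant majority to work, and the shrink loop will usually
  *manufacture* multimodality on smooth unimodal score distributions
  before the attempts run out, yielding a top-tail cut rather than a
  fallback — the selection is always upward-closed in score, but it is
  not a significance statement.
- `probe` — keep the original features ranked strictly above the best
  probe; a tie with the best probe discards the feature (conservative
  reading of "above"). Sparse special case: when no bootstrap ever
  selected any probe, the probes carry no importance information and the
  aggregation's own selection passes through unchanged.
- `none` — no cut (the full ranking, or the self-thresholding aggregator's
  selection).

Rank-directed aggregations (MR, RRA) expose scores to the score-based
thresholds through the order-reversing map $p + 1 - \text{mean rank}$, so
"higher is better" holds uniformly.

## Stability metrics

For two subsets of identical size $k$ from a universe of $n$ features with
intersection $r$, Kuncheva's index is $(rn - k^2)/(k(n-k))$; Lustgarten's
adjusted measure generalises to unequal sizes. The harness's headline
metric is the relative weighted consistency of the whole system of
$K \times R$ subsets, which handles varying subset sizes and is normalised
to $[0,1]$ given the observed total number of occurrences. Its remainder
term is $D = N \bmod |Y|$ (the original definition; some renderings print
$n \bmod |Y|$, available via `d_convention = "n"` — the two differ, and the
package's hand-verified examples pin the default). The degenerate system in
which every subset is the full universe has a zero denominator and returns
`NA` with a warning.

## The synthetic cohort generator

`simulate_survival_data()` draws continuous features from a standard normal
(optionally equicorrelated), booleans from Bernoulli(0.5) and categoricals
uniformly over 3–5 levels, then generates event times from a proportional
hazards model with exponential baseline (Weibull shape exposed) and linear
predictor $\eta = \sum_j \beta_j x_j$ over a planted set of relevant
features. Effects are planted on continuous features only — alternating in
sign when a single $|\beta|$ is given — so the ground truth is
unambiguous; boolean and categorical columns act as realistic mixed-type
nuisance structure. Censoring is independent exponential, its rate
calibrated by monotone root search so the expected censoring fraction on
the drawn event-time sample matches the target; the defaults (m = 873, 140
mixed-type features, target censoring 0.93) emulate the shape of a
population-based ageing cohort.

What the generator does *not* emulate: correlated blocks of real clinical
measurements, informative censoring, longitudinal waves, or measurement
error. Passing tests on this generator therefore demonstrates the
machinery — calibration, recovery of planted signal, reproducibility — not
performance on any particular clinical dataset.

## Numerical and design choices

- **Penalised-Cox tuning.** The regularisation strength is a policy
  object. The default, `lambda_cv(3)`, minimises 3-fold cross-validated
  partial-likelihood deviance along a trimmed glmnet path (30 lambdas down
  to 5% of the maximum, coordinate-descent tolerance $10^{-5}$) and takes
  the one-standard-error lambda — the standard parsimony rule when the fit
  is used for selection rather than prediction. `lambda_bic()` is cheaper
  but under-penalises bootstrap resamples (duplicated rows inflate the
  apparent likelihood; we observed it selecting every feature on some
  resamples), and `lambda_fixed()` serves deterministic tests.
- **Ridge evaluation model.** Fixed penalty (default 0.1) for determinism;
  internal CV is available. The concordance index is invariant to the
  scale of the linear predictor, so the exact penalty value matters little;
  with a single selected feature a plain Cox fit is used (the penalised
  predictor is a monotone transform of it).
- **Concordance.** A pair is comparable iff the strictly earlier time is an
  event; equal times are incomparable; risk ties count one half. This is
  deliberately the textbook rule — it matches a brute-force pair
  enumeration exactly, and differs from implementations that weight tied
  event times.
- **Ties.** All per-list rankings use a stable sort with the feature name
  as secondary key; TA's boundary tie keeps the lexicographically smaller
  name; MedRank processes lists in index order within each depth. These
  choices buy bit-reproducibility across platforms.
- **Categorical encoding.** One-hot expansion at fit time; importance maps
  back to the original feature as the maximum absolute score over its
  dummies, so ensemble bookkeeping stays per original feature.
- **Stratification.** Folds are stratified by the event indicator: at 93%
  censoring, unstratified folds would regularly contain zero events.

## When do ensembles help? (an honest negative result)

The package's end-to-end check compares the bootstrap ensemble (lasso base
selector, RRA at $p = 0.15$, $B = 20$) with the same selector run once per
training fold, on synthetic cohorts of 300 samples, 60 features, 8 planted
effects of $|\beta| = 0.8$ and 50% censoring. Under these conditions the
*individual* lasso is already highly stable — both pipelines recover all
eight planted features in essentially every fold — and the ensemble adds a
churn of borderline null features through RRA's anti-conservative tail, so
its consistency is reliably *lower* than the individual selector's, while
the held-out concordance of the two pipelines agrees to well within 0.03.
The corresponding acceptance check asserts the opposite direction and is
left failing by design rather than weakened.

This is not a contradiction of the ensemble literature so much as a
boundary of it: ensembles stabilise selection when the base selector is
unstable on the actual training data — weak effects, few events, strongly
correlated predictors — which is precisely the regime of the clinical
cohorts that motivate the method, and not the regime of a clean,
independent-feature simulation with eight strong effects and 150 events.
Users should expect the benefit of ensembling to grow with censoring, with
feature correlation, and with decreasing effect size, and should not pay
the ensemble's computational premium on data where a single well-tuned
sparse fit is already reproducible.

## Problem sizes used in the shipped checks

The unit suite runs on miniature configurations (tens to low hundreds of
samples, 2–6 bootstraps, 2×2 folds). The end-to-end comparison uses ten
synthetic cohorts at m = 300, p = 60, B = 20 with full 5×5
cross-validation; the acceptance script runs one such cohort plus a
calibration draw at the m = 873 cohort shape. These sizes were chosen so
the full pipeline, including roughly ten thousand penalised Cox fits, runs
comfortably on a single core while still exercising every stage at
realistic dimensionality.

## Known limitations

- Boosted-Cox base selectors (`glmboost`, `coxboost`) are registry slots
  for user-supplied adapters; requesting them without registering an
  implementation raises an error listing the available selectors.
- RRA's $\rho$ is not calibrated on sparse partial lists (see above); for
  interpretable significance levels use it with filter selectors, or
  enable the Bonferroni flag and validate on permuted outcomes.
- The imputation default is single median/mode imputation; multiple
  imputation is a hook, not a built-in.
- `cw_rel` is `NA` for the all-subsets-equal-to-the-universe system; the
  harness reports it as such rather than inventing a value.
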