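---
title: "Auditing clinical risk models with partial dependence, Shapley attribution, and directional concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing clinical risk models with partial dependence, Shapley attribution, and directional concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Tree-ensemble risk models for 30-day surgical complications are accurate
enough to be useful and opaque enough to be distrusted. Two post-hoc lenses
dominate practice: partial dependence plots (PDPs), which show the
population-average predicted risk as one or two features are varied, and
Shapley additive attributions, which decompose a single patient's prediction
into per-feature contributions. They answer different questions — "where do
population risk thresholds sit?" versus "why is this patient's risk what it
is?" — and before either is used for guideline development the two views
should be checked against each other. `pdpaudit` implements that audit as a
pipeline: permutation-importance screening with a relative-influence
threshold, 1D/2D partial dependence with bootstrap uncertainty, Monte-Carlo
Shapley attribution in log-odds units, and a per-feature directional
concordance statistic comparing PDP trend signs with Spearman correlations
between feature values and attributions.

The registry data such models are trained on (national surgical-registry
total-joint-arthroplasty extracts of ~500k cases) is proprietary, so the
package ships a synthetic cohort generator that emulates the registry's
*structure* — marginals, sentinel missing codes, the `"90+"` age token,
implausible values, a ~6.7% composite outcome — with a *known* planted
logistic truth. Every stage of the audit is therefore testable end to end:
the generator defines what the correct answer is, and the audit must recover
it.

## The synthetic cohort generator

`default_nsqip_specs()` declares 20 predictors (demographics, comorbidities,
preoperative labs, surgical factors) with the marginal means/SDs,
prevalences, missingness rates and expected risk directions reported for a
517,826-case registry TJA cohort. Continuous features are drawn from
truncated normals (truncation bounds wide enough that means shift by far less
than one standard error at the tested cohort sizes); binary and ordinal
features from their declared distributions. Ages of 90 and above are emitted
as the literal token `"90+"`, missing cells are stamped in completely at
random as sentinel codes (−99 for labs, −1 for the two high-missingness
categoricals), and 0.5% of rows receive one biologically implausible value in
a physiologically-filtered variable, so the cleaning path is always
exercised.

The outcome is Bernoulli with logit equal to a calibrated intercept plus a
linear predictor on z-standardised features. `default_ground_truth()` plants
a nonzero main effect on all 20 predictors (0.2–0.4 log-odds per SD, signs
matching each feature's expected direction) and five interaction effects on
the pairs found dominant in registry analyses: age × ASA (+0.45),
operative time × ASA (+0.35), operative time × age (+0.30),
hematocrit × ASA (−0.30) and hematocrit × diabetes (−0.30); the negative
signs encode risk amplification when *low* hematocrit meets high ASA class
or diabetes. `calibrate_intercept()` fixes the intercept by monotone root
search so simulated prevalence lands within 0.3 percentage points of the
6.7% target (the check widens only if the probe's own binomial noise exceeds
that band).

Features are drawn independently by default; an optional Gaussian copula
(`correlation =`) imposes dependence (e.g. age–ASA) for stress-testing the
concordance statistic. The registry reports marginals only, so any
dependence structure is a modelling choice, and independent draws keep the
oracle tests clean.

What the generator does **not** emulate: informative missingness,
measurement error correlated with outcome, site effects, temporal drift, or
the registry's true inter-feature dependence. Passing recovery tests
therefore demonstrates that the audit machinery is correct, not that any
particular clinical conclusion transfers to real registry data.

### The concordance-recovery preset

`ground_truth_recovery()` is the study condition for directional-concordance
recovery: purely additive monotone effects, each at least 0.2 log-odds per
SD, planted on the 12 predictors whose post-preprocessing information content
can support sign recovery (minority-class prevalence ≥ 5%, missingness
≤ 45%). Ultra-rare binaries (weight loss at 0.1% prevalence, CHF at 1.8%,
functional dependence at 2%, …) and the 90.2%-missing A1c get zero
coefficients: after median/mode imputation a realistic cohort cannot inform
their direction, so planting effects there would test the data, not the
method. This subset was fixed a priori from the marginals above, not fitted
to any test outcome.

## Preprocessing

`recode_sentinels()` maps `"90+"` to the numeric value 90 (a value, not a
missing datum) and sentinel codes to proper missing values.
`apply_physiologic_filters()` drops rows with BMI outside (10, 80) kg/m²,
operative time above 720 min, hematocrit outside (15, 60)%, albumin outside
(1, 6) g/dL, or A1c outside (4, 20)%. Bounds are read strictly — a BMI of
exactly 10 is retained — because "less than 10 or greater than 80" is the
literal rule and exactness is testable. Missing values never trigger
removal; no patient is excluded for missingness.

Baseline imputation is the median, computed over *training* rows only (the
natural leakage-free reading; medians this robust barely differ either way).
Binary/ordinal missing cells become an explicit "missing" category coded
`max(levels) + 1` — the treatment used for the two 60.7%-missing
categoricals and applied uniformly. `impute_chained()` provides
chained-equations multiple imputation as the sensitivity alternative: 10
sweeps, features visited in descending missing rate, stochastic linear draws
for continuous targets and Bernoulli-logistic draws for binary targets, with
a logged median/mode fallback for singular conditional fits. These settings
are package choices; the sensitivity analysis they support showed (on
registry data) a negligible AUC difference versus median imputation, which
is why the pipeline's default is the median.

`stratified_split()` allocates each outcome class independently
(nearest-integer rounding, remainder to training), which preserves the
complication rate to within one patient per class — at 50,000 patients the
train/test rate gap is below 0.01 percentage points.

## Models

The risk model is an off-the-shelf probability Random Forest (`ranger`)
behind a fixed contract: `predict_risk()` returns probabilities clipped to
`[1e-6, 1 - 1e-6]`, deterministically. Tuning follows the declared ranges
(trees 100–300, depth 5–15, minimum split size 5–15, minimum leaf size 2–8)
on a grid of endpoints plus midpoints, with stratified 5-fold CV on a
stratified subsample (12.1% of training rows, capped at 50,000) and a final
refit on all training rows. The grid density is a package choice — the
ranges are stated, a 3-point-per-axis grid (81 configurations) is the
default, and every recovery study in the test suite pins a single
mid-range configuration instead, since hyperparameter search is orthogonal
to what those studies measure.

The interaction model appends 24 product columns `z(a)·z(b)`, standardised
by training-row statistics stored in an `interaction_spec` so columns are
exactly reproducible on any table. The default pair list combines the six
clinically named pairs, the five dominant registry pairs (one overlaps), and
14 declared fillers. `interaction_risk_model()` wraps the fitted forest so
that partial dependence clamps *base* features and rebuilds every product
they enter — without this, clamping age would leave age × ASA frozen and the
surface would be inconsistent. Permutation importance deliberately does the
opposite: it shuffles the 44 columns independently, because the question
there is how much each *column* contributes to discrimination.

Predicted probabilities are not calibrated; attributions, binary PDP gaps
and archetype positions all work on uncalibrated scores or their log-odds.

## Interpretability machinery and its numerical choices

**Permutation importance.** Thirty independent within-column shuffles of a
fixed evaluation set (no row resampling — the repetition is over shuffles),
measuring the AUC drop. Relative influence normalises positive mean drops to
sum to one; negative drops are retained in the records but contribute zero
mass. The 5% relative-influence threshold (strict inequality) gates which
features get detailed PDP analysis, and `threshold_select()` decomposes the
selected influence into interaction vs main-effect shares, both as fractions
of total model influence and within the selected set.

**Partial dependence.** Grids span the 5th–95th percentile of the background
(per feature, falling back to the full range when heavy imputation collapses
the percentile window); binary and ordinal features are evaluated at their
levels only, never interpolated, with binary effects reported as level-1
minus level-0 log-odds gaps. Both probability and log-odds scales are
supported since both conventions appear in practice; on the log-odds scale,
per-row predictions are logit-transformed *before* averaging (the mean of
log-odds, not the log-odds of the mean). 2D surfaces subsample the
background without replacement (default 5,000 rows) and clamp both features
over the grid product. Bootstrap bands use 50 resamples of 2,000 rows with
replacement, recomputing the curve on the fixed full-background grid and
taking per-point percentile intervals. Trend direction is the least-squares
slope of curve values on the grid, with a dead zone: a total rise below
`1e-4` on the curve's scale is classified flat (sign 0). Brute-force
clamped-mean equality (to `1e-10`) is asserted in the tests.

**Monte-Carlo Shapley attribution.** Model-agnostic permutation sampling:
for each patient, sampled feature orderings are revealed one feature at a
time, with unrevealed features supplied by a paired background row
(marginal/interventional completion, which deliberately ignores feature
dependence). The pairing is balanced — every background row completes an
equal share of the orderings — which removes the background-sampling
variance component at no cost. Attributions are computed in log-odds of
clipped probabilities; the additive residual against the patient's actual
prediction is redistributed proportionally to absolute raw attributions so
efficiency (`base + Σφ = logit f(x)`) holds exactly per patient. Defaults:
200 permutations, 1,000 background rows. A tree-path-specific estimator was
rejected to stay backend-independent; exact enumeration over orderings and
background rows serves as the test oracle at 3 features.

**Directional concordance.** For each audited feature: the PDP trend sign;
the Spearman correlation (mid-rank ties, two-tailed t-approximate p on
n − 2 df) between feature values and attributions over a sampled patient set
(default 5,000); agreement when both signs are nonzero and equal. A flat PDP
counts as *dis*agreement and is flagged — a conservative choice, since a
genuinely flat dose–response cannot validate any direction. Pooled agreement
is reported unweighted and weighted by permutation relative influence
(negative-drop features get zero weight); the per-feature significance level
is Bonferroni-corrected (0.05/20 = 0.0025 for the default 20 predictors).
Ordinal features use their declared level coding as the Spearman "values",
which is the only ordering the specification of the feature provides.

**Archetypes.** Patients at the 10th/50th/90th percentile of predicted risk
(nearest-rank, lowest-index tie-break) are reported with their attributions
and their position on each display feature's population curve — the clamped
population-average at the patient's own value, not an interpolation.

**VIF.** `1/(1 − R²)` from least-squares regression of each standardised
design column on the others; perfect collinearity is reported as `Inf`
rather than an error, and medians are summarised separately for main effects
and interaction columns. High VIFs among products and their parents are
expected arithmetic, not a data problem.

## Problem sizes

The generator's study conditions (cohort n = 50,000, planted coefficient
magnitudes, the 6.7% prevalence, 0.5% implausible-value rate) are fixed.
Around them, the package chooses run sizes for its own studies: the recovery
suites use 10 generator seeds, a single mid-range forest configuration
(100 trees, depth 10), 5 importance repeats over 4,000 evaluation rows,
800-row PDP backgrounds with 15-point grids, and Shapley attribution for 400
patients at 20 permutations over 200 background rows. The default
`audit_config()` pipeline audits a 20,000-patient cohort with 10 importance
repeats, 500 Shapley patients at 30 permutations, and 50 × 2,000 bootstrap
bands on a 15-point grid. These sizes keep Monte-Carlo error comfortably
inside the margins the recovery criteria assert (e.g. interaction relative
influences of 6–19% against a 5% threshold) while a full run stays in the
minutes range on one core; all of them scale up through configuration
without touching code.

```{r, eval = FALSE}
library(pdpaudit)
summary <- run_pipeline(audit_config(n = 20000, seed = 1, out_dir = "audit_out"))
str(summary$decomposition)
```

## Known limitations

* Marginal Shapley completion and marginal PDP clamping both evaluate the
  model at feature combinations that may be off-manifold under dependence;
  the copula option exists precisely to study how much that distorts the
  concordance statistic, but no correction is applied.
* Relative influence is normalised over positive mean drops only; with many
  near-zero features the shares of small drops are noisy, which is why the
  threshold gate precedes any interpretation.
* The chained-equations imputer is a fixed-sweep stochastic regression
  scheme, adequate for sensitivity analysis but not a full MICE replacement
  (no predictive mean matching, no convergence diagnostics).
* The flat-PDP dead zone (`1e-4` total rise) and the probability clip
  (`1e-6`) are pragmatic constants; results are insensitive to them except
  for features the model essentially ignores, which the importance threshold
  removes from interpretation anyway.
* Synthetic recovery shows correctness of the machinery, not clinical
  validity of any threshold read off a PDP fitted to real data.
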