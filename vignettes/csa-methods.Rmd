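---
title: "Shapley-guided backward elimination for binary EHR cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shapley-guided backward elimination for binary EHR cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(shapCSA)
```

## The problem and the data model

Rare autoimmune neurologic diseases such as stiff person syndrome leave a
trail in the electronic health record long before a confirmed diagnosis:
the problem list. `shapCSA` works on exactly that representation — each
patient is a binary vector over the union of past-medical-history items
(1 if the item ever appears, 0 otherwise) plus a case/control label. The
central container, `CohortExperiment`, extends `SummarizedExperiment`
(features as rows, patients as columns) with a validity check that entries
are strictly 0/1, names are unique, and both classes are present.

At the scale this package targets — tens of patients against hundreds of
items — per-item association tests are underpowered and multiple-testing
corrections would erase everything. The package instead asks a multivariate
classifier which small subset of items jointly discriminates the classes,
and attributes the classifier's decisions to items with Shapley values.

## The model

The classifier is a soft-margin SVM with a Gaussian kernel,
$K(x, x') = \exp(-\gamma \lVert x - x'\rVert^2)$, fit by libsvm (via
`e1071`). Hyperparameters are deliberately plain and are echoed into every
output's provenance block:

* `C = 1` — the standard soft-margin penalty default;
* `gamma = "scale"` — resolved as $1/(p \cdot \mathrm{Var}(X))$ from the
  training matrix, a widely used default that adapts to sparsity of the
  0/1 entries;
* `classWeight = "none"` — the target cohort is nearly balanced (23/25);
  `"balanced"` is available for skewed ingested cohorts.

All downstream quantities (AUC, SHAP) use the signed decision margin
directly; no probability calibration is performed, which avoids an extra
estimation step that small folds cannot support. Predicted label is case
iff the margin is strictly positive.

## Shapley attribution

For one explained patient $x$, the coalition game is interventional:
$v(S)$ is the mean model score over hybrid rows that take $x$'s values on
the features in $S$ and each background row's values elsewhere. This is
well defined for binary features and requires only
$O(|\mathrm{background}|)$ model evaluations per coalition. Two estimators
share this value function:

* `exactShapley()` enumerates all $2^M$ coalitions ($M \le 15$) and applies
  the Shapley formula directly — the oracle.
* `kernelShap()` solves the weighted least squares over coalition masks
  with the Shapley kernel weight
  $\pi(s) = (M-1)/\binom{M}{s} s (M-s)$, with the efficiency constraint
  $\sum_i \phi_i = v(F) - v(\emptyset)$ eliminated into the design, so
  local accuracy holds exactly on every returned vector. Under full
  enumeration the solution coincides with the exact values (the test suite
  verifies agreement within $10^{-5}$ over 200 random games).

Sampling, when the budget is below $2^M - 2$: strata are coalition sizes;
the smallest/largest sizes (highest kernel mass) are enumerated
exhaustively while they fit the budget, and the remainder is sampled with
probability proportional to the per-size mass, duplicates collapsed by
weight. One design choice deserves emphasis: when fewer coalitions than
features are available the regression is solved by minimum-norm least
squares (SVD pseudoinverse) rather than refused. The loop over hundreds of
features would otherwise need a budget that grows linearly with $M$ even
though only the *ranking tail* — which feature is least important — matters
at large $M$; the minimum-norm estimate is deterministic, respects
efficiency, and converges to the exact values as the budget grows. The
alternative (L1-regularised selection, as the reference Kernel SHAP
implementation uses in this regime) introduces a tuning parameter we would
have to pick blindly.

Background sets are the training rows of the current CV fold, subsampled
deterministically to `backgroundSize` (default 16). Attributions for
ranking are computed on **held-out** rows and pooled across folds and
repetitions, consistent with how performance is assessed; the same applies
to the final beeswarm export (`explainFinal()`), i.e. the reported
interpretation never uses in-sample attributions.

## Cross-validation and uncertainty

`stratifiedKFold()` deals each class round-robin after a seeded shuffle
(per-fold class counts within one of perfect stratification), repeated
`repeats` times with derived seeds. The five metrics — precision,
sensitivity, F1, accuracy, AUC (Mann–Whitney with midranks on the margins)
— are computed on predictions pooled across repetitions: per-repetition
averaging is ill-defined for AUC when folds contain a handful of cases.

Confidence intervals come from a cluster bootstrap over patients: each of
the `rounds` (default 200) resamples draws patients with replacement and
carries all their pooled predictions, respecting the patient as the
sampling unit without refitting models. The number of repetitions (default
5) is a compromise: it stabilises fold noise at 48 patients while keeping
a full 319-feature sweep affordable. Bootstrapping predictions, patients or whole CV splits would each be
defensible; the patient-level scheme is this package's definition and is
documented as such.

## The CSA loop and the selection rule

Each iteration of `runCSA()` cross-validates the current feature set,
aggregates held-out mean $|\phi|$ per feature, records the metrics with
CIs, and removes the feature with the smallest importance — ties broken by
lexicographically smallest name, which matters for binary features where
exact ties occur. Feature sets are therefore strictly nested and the trace
has exactly $M - \mathrm{minFeatures} + 1$ records; the run is
deterministic given cohort, config and seed, and the trace TSV is rewritten
after every iteration so an interrupted run leaves a usable partial trace.

`selectOptimal()` implements a most-metrics-won decision rule: each metric is
won by the record(s) attaining its maximum point estimate (all ties win);
the record with the most metric wins is selected, ties resolved toward
fewer features. CIs are reported but never used for selection.

## The synthetic cohort generator

`simulateCohort()` emulates the kind of cohort this pipeline was built
for: 23 cases and 25 controls over 319 binary items by default. Planted
informative features are Bernoulli with class-specific prevalences; all
other features draw a single background prevalence from Beta(0.6, 5)
(median ≈ 0.08, i.e. most items are rare — the sparsity signature of real
problem lists) shared by both classes. Features are independent by
default; an optional block-correlation extension (features copying a
shared latent Bernoulli with probability `rho`) exists because real
problem-list items co-occur, but it is off by default and not used in any
shipped check. A lognormal per-class serum-titer covariate can be attached
as metadata to exercise the continuous arm of the demographics table.

What passing tests on these cohorts do **not** show: robustness to
correlated comorbidity blocks, to label noise (misdiagnosed controls), to
missingness in problem lists, or to vocabulary drift between sites. The
generator is a positive control for the machinery, not a claim about EHR
realism.

## Cohort statistics

The demographics table uses two-sided Fisher's exact tests computed by
explicit enumeration over the feasible range of one cell — the p-value is
the sum of hypergeometric point probabilities not exceeding the observed
one, within relative tolerance $10^{-7}$ (the SPSS/R convention; the
doubling convention is deliberately not implemented). Welch's t statistic
is computed from group summaries with Welch–Satterthwaite degrees of
freedom, so published mean/SD/n rows can be checked without patient-level
data. Display follows the field's convention: `k/n (pct)` with percentages
rounded half away from zero, p-values to three decimals.

## Numerical and degenerate-input choices

* Fisher with a zero margin: p defined as 1 with a warning (the test is
  vacuous).
* Welch with two zero-variance groups: t = 0, p = 1 when means agree,
  p = 0 otherwise.
* No predicted positives: precision defined 0 with a warning (F1 follows).
* Constant scores: AUC 0.5 by the midrank convention.
* Bootstrap resamples missing a class are redrawn (up to 1000 attempts)
  before erroring.
* All stochastic stages draw named seeds derived from one master seed, so
  a single integer reproduces cohort, folds, coalition samples and
  bootstrap draws bit-for-bit.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full 319-feature sweep at
reduced budgets chosen as the smallest that leave the loop's behaviour
intact: 1 CV repetition, 64 sampled coalitions, background 8, 20 bootstrap
rounds (a few minutes on one CPU). The planted-recovery check keeps the
default 5 CV repetitions — fewer repetitions coarsen the pooled-metric grid
enough to change which feature-set size wins — while reducing only the
attribution budget; null-calibration checks use 15-feature cohorts with a
single repetition. These sizes are
the package's own verification choices; scientific use should keep the
defaults (5 repetitions, `"auto"` coalition budget, 200 bootstrap rounds).

## Known limitations

* Backward elimination is greedy: a feature informative only jointly with
  another can be eliminated early; no forward or floating variant is
  provided.
* At small cohort sizes the most-metrics-won selection rule often prefers
  very compact models: when each informative item classifies well on its
  own, a one- or two-feature record can attain the maximum point estimate
  of several metrics, so the selected set may contain fewer informative
  features than the data hold even when the elimination ordering ranks
  all of them at the top. Inspect the trace tail, not only the selected
  set, when characterizing a cohort.
* The minimum-norm Kernel SHAP estimate at very small budgets biases
  attributions toward equal spread within sampled coalitions; rankings at
  the elimination margin are correspondingly noisy at large $M$.
* Metrics are pooled over repetitions, so bootstrap CIs reflect resampling
  of patients, not of CV partitions.
* No nested hyperparameter tuning: C and gamma are fixed defaults, and the
  selection rule compares feature sets under those defaults only.
* Interrupted runs resume manually from the partial trace file; there is
  no automatic checkpoint restore.
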