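---
title: "Sensitive-period analysis with conditional inference forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensitive-period analysis with conditional inference forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensewin)
```

## The problem

Brain regions mature on different schedules, and a region changing
rapidly at a given age may be especially vulnerable to adversity
experienced at that age.  Given a cohort of maltreated children with,
for each child, a year-by-year binary exposure history (plus a prenatal
domestic-violence flag, the maltreatment types experienced, and the
total exposure duration) and a continuous regional gray-matter summary
(a cluster eigenvariate), the question is: *exposure at which ages best
predicts the regional signal?*  An age bin whose exposure indicator
carries high predictive importance is a candidate **sensitive period**.

Ordinary regression is poorly suited here: the annual exposure
indicators are strongly serially correlated (episodes span many years),
the cohort is small, and effects need not be linear or additive.
`sensewin` therefore implements the standard machinery used for this
design — random-forest regression with conditional inference trees,
permutation variable importance, and a re-randomization significance
test — as a reusable, fully seeded package, together with a synthetic
cohort generator so every stage is testable without clinical data.

## The model

### Conditional inference trees

Each base learner selects its split variable by a permutation-test
association statistic rather than impurity gain, which removes the
selection bias toward predictors with many distinct values.  At a node
holding responses $y_1,\dots,y_n$ and a candidate predictor $x$, the
linear statistic is

$$T = \sum_{i=1}^n x_i\,(y_i - \bar y),$$

whose exact conditional moments under random permutation of the
response are $\mathbb E[T] = 0$ and

$$\operatorname{Var}[T] \;=\; \frac{1}{n-1}
  \sum_i (x_i - \bar x)^2 \;\sum_i (y_i - \bar y)^2 .$$

The standardized score $|T|/\sqrt{\operatorname{Var}[T]}$ is referred to
the standard normal for a two-sided p-value.  At each node `mtry`
candidates are drawn at random; the candidate with the smallest p-value
is selected (ties to the lowest column index) after a Bonferroni
adjustment over the candidates, and the node is split at the cutpoint
maximizing the standardized two-sample statistic among all midpoints
between consecutive distinct values whose children both satisfy
`min_bucket`.  Cases equal to the threshold go left (`x <= t`); tied
split statistics keep the smallest threshold.  Terminal predictions are
node means.

**Accuracy of the normal approximation.**  The conditional moments are
exact — the test suite verifies them against exhaustive enumeration of
all $n!$ permutations at machine precision — but the two-sided normal
tail is only an approximation to the discrete permutation law.  For
$6 \le n \le 8$ the approximate and exhaustive p-values agree within
0.4 in our checks; below $n = 6$ the approximation is qualitative and
should be read only as a ranking device.  This matters little in forest
mode, where `alpha = 1` disables p-value-based stopping and the
p-values only *order* candidates; it matters if trees are used
stand-alone with small `alpha` at very small node sizes.

### The forest

`n_trees` (default 200) unpruned trees are grown, each on a
without-replacement subsample of fraction 0.632 of the cases, with
fresh candidate draws at every node.  Predictions are the unweighted
mean of tree predictions.  (The classical cforest aggregates case
weights; with regression trees and node-mean predictions the unweighted
mean is equivalent for single trees and simpler to reason about for
ensembles; the difference is a design choice documented here.)  Cases
outside a tree's subsample are its out-of-bag (OOB) cases; with 200
trees and fraction 0.632 the probability a case is never OOB is
$0.632^{200} \approx 10^{-40}$, so OOB predictions exist for every case
in practice.

Defaults `min_split = 8`, `min_bucket = 3`, `alpha = 1` (no early
stopping) reflect the very small cohorts this design targets
(n ≈ 20–50): they allow two or three splits per tree at n = 21 while
keeping terminal means estimable.  All values are configurable and
recorded in every report and log.

### Permutation importance

Importance of predictor $j$ is the mean over trees of the increase in
the tree's OOB mean squared error after permuting column $j$ among that
tree's OOB cases (`n_perm` permutations averaged, default 1 — the
ensemble of 200 trees absorbs the permutation noise).  A tree that
never split on $j$ contributes exactly zero.  Negative values are
reported untruncated; bar-chart displays conventionally floor at zero,
but truncation inside the statistics would bias the null comparisons
below.

This is the *marginal* permutation scheme.  Its known limitation: when
predictors are correlated — and annual exposure bins are, strongly —
permuting one column produces covariate combinations off the joint data
manifold, which inflates MSE slightly regardless of the response.
Under a null cohort (no effect anywhere) the age-bin importances are
therefore not mean-zero but carry a small positive offset (about 1 MSE
unit against a response variance of 100 in our simulations, i.e. ~1%).
With mutually independent predictors the same pipeline is unbiased (a
property test covers this).  The *conditional* permutation variant that
removes the offset is deliberately out of scope; all significance
statements below are calibrated against a null that shares the offset,
so they are unaffected.

### Re-randomization inference

Could the peak importance have arisen by chance?  The null is built by
re-randomization: permute the response across subjects (leaving the
correlated predictor matrix intact — this preserves the inter-predictor
dependence under the null, which is essential given the offset above),
refit the entire forest, and recompute the importance profile, $B$
times (default 10,000 in production; 99–499 in tests and examples).
Three tests are derived from the same $B$ profiles:

* **Max-importance test** — statistic: the maximum observed importance
  over the predictor set of interest (the age bins in the timing
  design, all five predictors in the type design); null draws: the
  maxima over the same set per re-randomized profile; p-value: the
  add-one estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$,
  which is never smaller than $1/(B+1)$ and is valid by construction.
* **Marginal per-predictor p-values** — each observed importance
  against its own null column, same estimator, then Benjamini–Hochberg
  step-up FDR adjustment across the age bins of a design (or within
  each symptom subscale).  The FDR family choice and the BH (rather
  than BY) procedure are design decisions of this package.
* **Combined-window test** — statistic: the summed observed importance
  over a contiguous block of age bins; null draws: the *maximum over
  all contiguous windows of the same length* of the summed null
  importances, so the p-value accounts for having selected the
  best-looking window.  This is one defensible reconstruction of a
  "combined degree of importance" test for a multi-year peak; the sum
  is not the only possible combining function.

On a singleton predictor set the max test reduces exactly to the
marginal p-value (tested).  The empirical size of both tests under the
null generator is checked at $\alpha = 0.05$ with 200 outer replicates
at $B = 99$, 50 trees, n = 100 — sizes chosen so the whole suite runs
in minutes; validity of the add-one estimator does not depend on $B$.

### Signal preparation

`scale_signal` centers and scales to the conventional arbitrary mean
100 / SD 10 (sample SD, $n-1$); it is idempotent and refuses constant
input.  `cluster_eigenvariate` reduces a subjects × voxels cluster
matrix to one value per subject: the first left singular vector of the
column-centered matrix scaled by its singular value, sign-fixed to
correlate positively with the subject-wise mean signal.  Upstream
voxel-based morphometry (segmentation, registration, smoothing, the
group contrast that defines the cluster) is out of scope; the pipeline
begins at the extracted cluster matrix or eigenvariate.

The OOB prediction correlation `prediction_r` reported with every
analysis uses out-of-bag predictions: in-sample forest predictions are
optimistically near 1 by construction and would overstate fit.

## The synthetic cohort generator

`sim_config()` + `simulate_cohort()` emulate the exposure structure the
analysis assumes:

* **Episodes** are single contiguous runs: onset drawn from
  `onset_distribution` (default uniform over the 16 annual bins),
  each subsequent year exposed with probability `episode_persistence`
  (default 0.98).  With these defaults the mean exposure duration is
  ≈ 7.5 years with SD ≈ 4.5, matching the long multi-year exposures
  (7.7 ± 4.68 y) such cohorts report.  The bin count is configurable;
  16 annual bins (birth through age 16) plus the prenatal flag and
  duration give the 18 timing predictors.
* **Types** (physical, emotional, sexual, neglect) are independent
  Bernoulli draws with prevalences 7/21, 11/21, 2/21, 16/21 — the
  observed cohort rates.  Any positive type triggers an exposure
  episode; a subject with no type has an all-zero history.  Cross-type
  correlation is not modeled (a config extension).
* **Prenatal domestic-violence exposure** has prevalence 0.2 by
  default — no published rate accompanies the cohort; 0.2 is a
  plausible mid-range figure for maltreatment samples and the value is
  inert (the default response model gives it no effect).
* **Response**: `y = -effect_size × (exposed years inside
  effect_window) + type_effect × n_types + N(0, noise_sd)`, with
  `effect_window = {5, 6}` (ages 5–7), `effect_size = 1`,
  `noise_sd = 1` — one noise-SD of signal loss per exposed window
  year — and `type_effect = 0`.  The TSCC option adds six subscale
  responses; anxiety, post-traumatic stress and dissociation share the
  timing effect, the others are pure noise.

What the generator does **not** emulate: multi-episode histories,
reporting error in retrospective exposure timing, type-specific timing
effects, floor/ceiling effects in symptom scales, and the covariate
structure (age, sex, IQ, brain volume) regressed out upstream.  A
passing recovery test on synthetic cohorts therefore demonstrates that
the machinery detects the kind of window effect it models — not that
any particular clinical dataset contains one.

## Numerical and reproducibility choices

* All randomness in the tree/forest/importance/re-randomization engine
  flows through a splitmix64 counter RNG, independent of R's RNG and
  identical across platforms.  Streams split hierarchically:
  forest seed → per-tree seed → per-node seeds (children keyed left/
  right), and importance permutations are keyed by (tree, predictor,
  repetition).  Two consequences are tested: shrinking `alpha` can
  only prune, never restructure, a tree (depth is monotone in
  `alpha`), and restricting or reordering the predictor set of an
  importance evaluation relabels rather than changes results.
* The cohort generator uses R's RNG, seeded once per cohort from
  `sim_config$seed`, and restores the caller's RNG state.
* Degenerate inputs: zero-variance predictors score statistic 0 /
  p-value 1 and are never split on; constant responses yield root-only
  trees; add-one p-values never reach 0; variance comparisons use an
  absolute tolerance of $10^{-12}$.
* Monte-Carlo test sizes (50-tree forests, B = 99–499, n = 100–200,
  10–200 replicates) are package choices balancing statistical
  resolution against a test suite that completes in minutes; the
  production defaults (200 trees, B = 10,000) are what an analysis of
  a real cohort should use.

## Limitations

* Marginal (not conditional) permutation importance: see above; peak
  *locations* among highly correlated neighboring bins should be read
  as windows (hence the combined-window test), not single years.
* Asymptotic node p-values are unreliable below n ≈ 6; with the
  forest defaults they are used only to rank candidates.
* Regression only; no categorical multi-level splits, no surrogate
  splits, no missing-data handling (readers reject missing values).
* The re-randomization test conditions on the predictor matrix; it
  tests the null of no y–history association, not model adequacy.
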