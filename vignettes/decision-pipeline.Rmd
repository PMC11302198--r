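---
title: "The physioscreen decision pipeline: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The physioscreen decision pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physioscreen)
```

## The problem

physioscreen implements a case-control decision pipeline for multimodal
wearable physiological data. The setting it targets is an adult ADHD
screening study: each participant — 44 neurotypical controls (CG) and 32
ADHD-diagnosed cases (EG) in the emulated design — completes six
computerized Stroop tests (three colour-word variants C1–C3, two number
variants N-S and N-V, one emotion variant E) while a wrist-worn sensor
records electrodermal activity (EDA), heart rate variability (HRV) and skin
temperature (ST). Each signal segment is summarized into a feature vector
(103 EDA + 77 HRV + 11 ST = 191 features per participant-test), and the
question is whether those features separate the two groups.

The pipeline has four stages:

1. **Screening** — decide which Stroop tests elicit exchangeable responses
   within a person (Wilcoxon signed-rank, bundling) and which test bundle
   best separates the groups (two-sample Kolmogorov–Smirnov).
2. **Informative point selection** — score every (participant, test) data
   point by an informative-KNN criterion and discard the least informative
   5%.
3. **Feature selection** — discard low-variance features by robust relative
   dispersion thresholds (rMAD, rIQR).
4. **Classification** — PCA followed by one of four classifiers (LR, KNN,
   RF, SVM), evaluated by Monte-Carlo stratified cross-validation, on the
   full and on the point-filtered ("reduced") dataset.

Because the underlying clinical dataset is not public, the package ships a
synthetic cohort generator that reproduces the statistical *structure* the
pipeline assumes, so every stage is testable end to end, plus the published
metric tables as a fixture for derived-quantity analyses.

## The synthetic cohort generator

`generate_cohort()` draws the value of feature $f$ for participant $i$ on
test $t$ of type $T$ as

$$x_{i,f,t} = \mu_f + a_i + b_{f,T} + \Delta\, z_{f,T}\,
  \mathbf{1}[i \in \mathrm{EG}] + \varepsilon_{i,f,t}$$

with per-feature baselines $\mu_f \sim N(0,1)$, participant random effects
$a_i \sim N(0, \sigma_s^2)$, per-(feature, test-type) offsets
$b_{f,T} \sim N(0, \sigma_T^2)$ shared by same-type tests, and residual
noise $\varepsilon \sim N(0, \sigma_w^2)$. Group effects are *planted*:
for each test type, `round(effect_fraction * 191)` features get
$z_{f,T} = 1$ and EG rows are shifted by
$\Delta = \texttt{effect\_size} \times \sigma_w$.

The defaults are the study conditions the pipeline is meant to recover:

* cohort bookkeeping 95 enrolled → 4 incomplete → 15 unretrievable → 76
  analyzed (44 CG / 32 EG); dropouts are generated and flagged, not
  omitted, so the recruitment flow is reproducible;
* effect fractions C 0.104, N 0.52, E 0.036 — the group signal concentrates
  in the number tests, mirroring the reported ~52% / ~10.4% / ~3.6%
  significant-feature rates;
* `effect_size = 1.5` residual standard deviations for affected features —
  a strong but not degenerate planted effect, chosen so that per-feature
  KS power at the emulated sample sizes (88 vs 64 pooled number-test rows)
  is high without being trivially saturated;
* $\sigma_s = 0.5$, $\sigma_T = 1$, $\sigma_w = 1$: the participant effect
  is half a residual SD (plausible inter-individual physiology), and the
  between-type shift equals one residual SD, which makes same-type pairs
  nearly exchangeable and cross-type pairs clearly shifted — the regime the
  bundling stage assumes;
* demographics: age Normal truncated at 18 with per-group means/SDs
  35.18 ± 11.14 and 32.58 ± 11.39; gender Bernoulli with male fractions
  32/58 and 24/37.

Marginals are Gaussian although real physiological features certainly are
not; every downstream statistic is rank-based, distribution-free or fitted
after standardization, so Gaussian structure is sufficient for the
properties being tested. What the generator deliberately does **not**
emulate: heavy-tailed or skewed feature marginals, correlation between
features within a modality, medication or comorbidity covariates, and any
actual signal morphology. Passing tests therefore demonstrate that the
*procedures* behave as specified on data with the assumed dependence
structure — not that real wearable data carries the planted effect sizes.

## Screening

**Within groups.** For every pair of tests and every feature,
`pairwise_within_group_ratio()` runs a two-sided Wilcoxon signed-rank test
on the participant-paired values and reports the fraction of features with
$P \le 0.1$. Zero differences are dropped before ranking (the classic
convention, as in `stats::wilcox.test`); a feature with all-zero
differences counts as non-significant; p-values use the normal
approximation with continuity correction. The cutoff is inclusive
($P \le \alpha$).

**Bundling.** `bundle_tests()` links two tests when their ratio is at most
`tau` in *both* groups and takes connected components; with the study-like
pattern (same-type ratios ≈ 0.05–0.1, cross-type ≈ 0.5–0.8) and the default
`tau = 0.2` this recovers `{C1, C2, C3} → C`, `{N-S, N-V} → N`,
`{E} → E`. Because the underlying bundling criterion is qualitative, the
fixed C/N/E map (`bundle_map_default()`) is the pipeline default and the
data-driven rule is the exploratory alternative.

**Between groups.** `ks_between_group_ratio()` pools the rows of a
bundle's member tests per group — deliberately treating repeated tests of
one participant as independent samples, replicating the original protocol;
this is a documented fidelity-over-purity choice — and runs a two-sample
two-sided KS test per feature, reporting overall and per-modality
significant-feature ratios and the argmax bundle. Asymptotic KS p-values
are used: the pooled sample sizes (88 vs 64 for the number bundle) are
comfortably asymptotic, and this matches the common scientific-Python
default at these sizes. Note the asymptotic two-sample KS test is slightly
conservative: its empirical rejection rate at $\alpha = 0.1$ under the null
is ≈ 0.08–0.09 rather than 0.10. The package's null-calibration check
accounts for this by testing that the Monte-Carlo mean ratio over 20 null
cohorts falls inside the 99% binomial band for a single 191-feature cohort,
which comfortably brackets the conservatism.

**Demographics.** `demographic_comparison()` uses the pooled-variance
two-sample t-test (df $= n_1 + n_2 - 2$, implied by the published degrees
of freedom) and a Yates-corrected chi-square on the 2×2 gender table — the
corrected statistic is the one that reproduces the published value 0.5221
on the published table (32/26 vs 24/13).

## Informative point selection

For each point $\mathbf{x}_i$ with label $y_i$, the k nearest neighbours
(Euclidean, self excluded) are scored by

$$P(\mathbf{x}_j \mid \mathbf{x}_i) = \frac{1}{C_i}\,
 d(\mathbf{x}_j, \mathbf{x}_i)^{\eta}\,
 \Lambda(\mathbf{x}_j, \mathbf{x}_i)^{1-\eta}, \qquad
 \Lambda = \prod_{n=1}^{k}\bigl(1 - d(\mathbf{x}_j, \mathbf{x}_n)
 (1 - \delta_{y_j, y_n})\bigr)$$

where $d$ is the Gaussian kernel similarity, $\eta$ is the fraction of
$\mathbf{x}_i$'s k neighbours sharing $\mathbf{x}_j$'s label, and $C_i$
normalizes the k masses to one. Ranking neighbours by $P$, the labels of
the top $M$ are majority-voted into a prediction $\tilde y_i$ and the
binary score $s = 1 - \delta_{y_i, \tilde y_i}$ is averaged over
$k \in \{3, 5, 7, 10\}$, $M \in [1, k]$ — 25 combinations — into
$\bar s(\mathbf{x}_i) \in [0, 1]$. High $\bar s$ marks a point that its own
neighbourhood consistently classifies into the other group;
`filter_points()` discards the worst `round(0.05 n)`.

Numerical and interpretive choices:

* **Standardization.** Features are z-scored before distances (default);
  the kernel is scale-sensitive and raw feature scales would let single
  features dominate.
* **Bandwidth.** The literal kernel $e^{-\lVert\Delta\rVert^2}$ underflows
  to zero for standardized vectors in 77–191 dimensions
  ($\lVert\Delta\rVert^2 \approx 2\,\mathrm{dim}$), making every similarity
  0 and the normalization degenerate. The default is therefore the median
  heuristic (bandwidth = median pairwise squared distance); the literal
  rule (`bandwidth_rule = "literal"`) is retained for low-dimensional work
  and for oracle tests. When all k masses still underflow to exactly zero
  the distribution falls back to uniform $1/k$ with a warning.
* **$\eta$.** Read as the fraction of the query's k neighbours (including
  the candidate itself) whose label equals the candidate's; under this
  reading $\eta \in [1/k, 1]$, and the exponent collapse cases
  ($\eta = 1 \Rightarrow P \propto d$) are exercised by tests.
* **Ties.** Neighbour ranking ties break by distance order (stable);
  even-$M$ vote ties resolve to the label of the single most informative
  neighbour; equal $\bar s$ at the discard boundary breaks by stable input
  order. Discard counts round half up.
* **Scope.** `"all-points"` (default) discards over the whole dataset;
  `"cg-only"` restricts candidates to controls — the reading in which only
  the unvetted control group can harbour mislabelled ADHD-like
  participants. Both are exposed because the two readings are equally
  defensible; neither is asserted as *the* original procedure.
* **Leakage.** The default protocol filters the complete dataset once,
  before cross-validation, so that every fold sees the same point set —
  replicating the original evaluation design. This leaks test-point
  geometry into the filtering decision; the `filter_train` option of
  `pipeline_config()` provides the leakage-free alternative (filter the
  training partition of each fold only).

The implementation is verified against an independent brute-force oracle
(direct loops over the three defining equations, no shared code) to
1e-12 on random 30-point instances, and satisfies two exact structural
properties: probability normalization per point and per k, and the
label-flip complement $\bar s \mapsto 1 - \bar s$ when only the point's own
label is flipped.

## Robust variance filters

$$\mathrm{rMAD}(\mathbf f) = \frac{\mathrm{med}(|\mathbf f -
\mathrm{med}(\mathbf f)|)}{|\mathrm{med}(\mathbf f)|}, \qquad
\mathrm{rIQR}(\mathbf f) = \frac{|p_{75} - p_{25}|}{|p_{25}|}$$

Features failing either lower bound are discarded. Percentiles use linear
interpolation between order statistics (`quantile` type 7), so
`rmad(1:5) = 1/3` and `riqr(1:5) = 1` are exact hand-checkable anchors.
When $p_{25} = 0$ the denominator switches to $p_{75}$; when the median is
zero, rMAD returns the unnormalized MAD with a degeneracy flag (the
relative form is undefined and the caveat published for rIQR has no rMAD
analogue, so the minimal-invention fallback is used). Absolute values in
the denominators keep both statistics nonnegative on negative-valued
features. During cross-validation the statistics are computed on training
rows only.

## Classification and evaluation

Per fold: stratified 70/30 split (per-class test counts round half up) →
variance thresholds fitted on the training rows → per-feature z-scoring
fitted on training → PCA fitted on training (components either by
cumulative-variance fraction, default 0.95, or a fixed count capped at the
training rank with a warning) → classifier fit → held-out scoring with EG
as the positive class. "100-fold cross-validation with a 70/30 split" is
necessarily *repeated random splitting* (Monte-Carlo CV) — a partition into
100 folds is impossible with at most 152 points — and that is what
`evaluate_config()` implements; fold $f$ is seeded `seed + f`, making the
whole pipeline bit-reproducible.

The four classifiers use the field-standard implementations: ridge
logistic regression (`glmnet`, with the inverse-regularization grid mapped
to `lambda = 1/(C n)`), `class::knn`, `randomForest`, and radial-kernel
`e1071::svm`. The original study names no hyperparameter values, so
`default_grids()` supplies modest expert-default grids (LR
$C \in \{0.01, 0.1, 1, 10\}$; KNN $k \in \{3,5,7,9\}$; RF trees
$\{100, 300\}$ × node cap $\{\infty, 32\}$; SVM cost $\{0.1, 1, 10\}$ ×
kernel width $\{1/p, 0.01, 0.1\}$), fully overridable.
`tune_and_evaluate()` evaluates every grid point — classifier
hyperparameters × (rMAD, rIQR) thresholds × PCA rule — under identical fold
seeds and selects by mean test accuracy. Whether the full or the reduced
point set is used is *not* a hyperparameter: each variant is tuned and
reported separately. Selection uses the same folds it reports
(in-sample model selection), replicating the original scheme; this is
known to yield optimistic estimates, which is why the package's claims
about filtering are phrased as *comparisons* between variants evaluated
identically.

Data points are (participant, test) rows, so the number bundle contributes
two points per participant and a point-level split can place one
participant on both sides of a fold. This replicates the original
granularity and is the default; `split_unit = "participant"` provides the
grouped split for users who want partition independence at the person
level.

`balanced_accuracy_change()` compares variants by balanced accuracy
$(\mathrm{sensitivity} + \mathrm{specificity})/2$ and reports, per
classifier, the mean relative change over the four datasets (EDA, HRV, ST,
fusion) in percent. Fed with the bundled published metric tables
(`load_printed_metrics()`), it reproduces the published mean relative
changes (LR ≈ 9.57%, RF ≈ 15.21%, KNN ≈ 14.23%, SVM ≈ 17.72%) by exact
arithmetic.

## Problem sizes used by the test suite

The suite exercises the full 191-feature, 76-participant default cohort
where the claim depends on it (bookkeeping, planted-effect recovery over
20 seeds, null calibration over 20 seeds) and deliberately smaller cohorts
(≈ 24–36 features, 26–36 participants) for property checks where the
property is size-free (symmetry, monotonicity, invariances), keeping the
default run fast while still covering the study-scale configuration. The
classifier sanity checks use two 5-dimensional Gaussian classes
(n = 120, separation 4 SD) for the separability bound, permuted labels for
the null, and a 200-point 5%-label-flipped benchmark for the
filter-improves-performance property.

## Known limitations

* The generator's independence across features understates the correlation
  of real physiological features; significant-feature *counts* on real
  data would be overdispersed relative to the binomial behaviour the tests
  assert on synthetic nulls.
* The i-KNN kernel's high-dimensional underflow is resolved here by the
  median heuristic; whether the original analysis scaled distances
  differently is unknown, so absolute $\bar s$ values are not comparable
  across bandwidth rules (rankings typically are).
* Published-table reproduction is limited to derived quantities (balanced
  accuracy and its relative change, the demographic statistics): absolute
  classification metrics require the original clinical dataset, which is
  not available.
* The claimed invariance of the screening ratios under monotone feature
  transforms holds exactly for the KS stage (a rank statistic); the
  Wilcoxon signed-rank stage is invariant to sign-preserving affine maps
  but not to arbitrary monotone transforms, since these reorder the
  magnitudes of paired differences. The test suite asserts the KS
  invariance only.
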