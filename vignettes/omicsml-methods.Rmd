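---
title: "omicsml: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{omicsml: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The pipeline and its assumptions

`omicsml` automates supervised learning on samples × features tables. The
pipeline order is fixed: load → omic pre-processing → train/test split →
quantile standardisation → feature selection → class balancing → tuning and
evaluation → best-model recommendation → plots and explanations. Two
assumptions run through everything:

* **The table is complete and numeric.** Missing cells are an error, never
  imputed; categorical features must arrive one-hot encoded. Silent
  imputation and silent factor coercion are the two easiest ways to destroy
  an omics analysis without noticing.
* **Only the training partition teaches.** The quantile maps, the univariate
  scores, the automated-k search, the rebalancing and all hyperparameter
  tuning see training rows only. The test suite asserts this by perturbing
  test rows and checking that every fitted object is bit-identical.

One run processes one data type; mixed omic/non-omic tables should be
pre-processed externally and loaded as `data_type = "none"`.

## Pre-processing parameters

All thresholds are configuration keys with conventional defaults:
`min_reads = 1000` and `norm_reads = 1000` (reads per sample),
`filter_abundance = 10` (total feature count across samples),
`filter_prevalence = 0.01` (fraction of samples in which a feature must be
observed), `test_size = 0.2`. Boundary semantics follow the words "fewer
than" / "less than": removal is strict (`< threshold`), retention inclusive.
"Coverage" in the sample-outlier filter means a value strictly greater than
zero, and the spread is the *population* standard deviation, so an exactly
homogeneous cohort removes nothing.

For raw counts (`expression_type = "COUNTS"`), TMM normalisation computes
per-library scaling factors: reference = library whose upper quartile of
depth-normalised counts is closest to the mean upper quartile; M-values
(log2 depth-normalised ratios) double-trimmed at 30% with a 5% trim on
A-values; precision-weighted mean of the retained M; factors rescaled to
geometric mean 1; output is counts per million of the effective library
sizes. Factor computation delegates to edgeR, the canonical implementation;
an independent transcription of the definition serves as the test oracle.
One subtlety the tests document: the *M-values and the trimmed set* are
exactly invariant to uniform depth scaling of a library, but the precision
weights (delta-method variances ≈ 1/count) are not, so factors move by
O(1/count) when depth changes — the suite asserts invariance at 1%, not
machine precision. All other expression types pass through unchanged.

Microbiome filters apply in a fixed order — taxonomy collapse, min-reads,
read rescaling, abundance, prevalence, metadata filters, class
removal/merging — because the filters do not commute and a reproducible
order matters more than any particular one.

## Standardisation

Each feature is mapped through its training empirical CDF onto [0, 1],
with `min(1000, n_train)` quantile grid points. This is robust to the
heavy-tailed, zero-inflated marginals typical of omics data, where
mean/variance scaling is dominated by outliers. Tied training values share
the midpoint of their probability range; values at or beyond the training
minimum/maximum map to exactly 0/1; constant features map to 0. The map is
monotone by construction, which also means tree learners are unaffected by
it — it exists for the distance- and margin-based learners (kNN) and for
comparability of attributions across features.

## Feature selection and the automated k

Univariate scores are the one-way ANOVA F (classification) and the
univariate linear-regression F = r²/(1−r²)·(n−2) (regression). Degenerate
cases are explicit: a constant feature scores 0 with a warning; a feature
with zero within-class variance but separated means scores +Inf and ranks
above every finite score; ties break by input column order, so selection is
deterministic.

The automated search evaluates 10 log-spaced candidate ks (endpoints always
included, rounded and de-duplicated) by 5-fold CV of a fixed-seed,
100-tree random forest on the k best features, using the run's configured
scoring metric. "Best performing and most stable window of three
consecutive candidates" is formalised as maximising mean − sd (score
metrics) or minimising mean + sd (error metrics) over the window scores,
with ties going to the better mean and then to the larger maximal k; the
chosen k is the window's largest member. The formalisation is a design
choice — the underlying idea is that a k whose neighbours perform poorly (a
"V" shape) earned its score by luck, and the sd term is what encodes that
caution. An exhaustive-enumeration oracle in the tests guarantees the
window rule is implemented exactly.

## Learners

No tree-ensemble, boosting or kNN package is available in the target
environment, so the registry is built on an in-package CART engine (Rcpp):
exhaustive midpoint split search over `mtry` sampled features, weighted
Gini or variance impurity, cover (summed training weight) tracked per node.
On top of it:

* `rf` — bagged trees, `mtry = √p` (classification) or `p/3` (regression),
  class probabilities = mean of leaf frequencies.
* `gradient_boosted_trees` — least-squares boosting for regression;
  logistic (binary) and softmax (multiclass, one tree per class per round)
  boosting with per-leaf Newton steps for classification. Defaults: 100
  rounds, learning rate 0.1, depth 3.
* `adaboost` — SAMME with depth-3 weighted trees (classification);
  AdaBoost.R2 with weighted-median aggregation (regression).
* `knn` — Euclidean k-nearest neighbours, k = 5 default.
* `lightgbm_style` — the boosting engine on histogram-binned features
  (quantile bins, `max_bin = 63` default), the defining LightGBM
  characteristic this environment lets us honour.

Search spaces follow fixed, documented tables (trees ∈ {100, 300, 500},
depths {0 = unlimited, 3, 6, 12, 20}, learning rates {0.3, 0.1, 0.03},
k ∈ {3, 5, 11, 21}, …); random search draws 20 seeded configurations
(the default configuration is always draw one), grid search is exhaustive
over the per-model grid, and every configuration is scored by the same
seeded, stratified 5-fold CV so comparisons are paired.

## Best-model recommendation

With `t` and `v` the train and test values of the configured metric and
`i` the ideal (1 for score-type metrics, which are bounded above by 1;
0 for error-type), the recommended model minimises

D = sqrt((t − i)² + (v − i)²) + |t − v| / √2.

The first term rewards absolute performance, the second (the perpendicular
distance to the y = x diagonal) penalises train/test divergence, i.e.
overfitting. Closeness-to-ideal and closeness-to-diagonal are combined as
an equally weighted sum — the simplest symmetric aggregate; both limiting
cases behave correctly (a perfect model has D = 0 and always wins; a pure
memoriser pays the full diagonal penalty). The rule lives in one function
(`best_model_distance`) so alternative aggregates are one-line swaps. Exact
ties (within 1e-12) resolve to registry order and are reported in
`best_model_tie_note.txt`.

A worked consequence, from the test suite: error-type points (0.02, 0.31)
and (0.30, 0.32) — the second wins (D ≈ 0.453 vs 0.516) despite the worse
test error, because the first is diagnosed as overfit.

## Explanations

Tree ensembles are explained with exact path-dependent tree-path Shapley
attribution, implemented in compiled code and verified against brute-force
subset enumeration on small trees. Additivity —
`base + Σ_j attribution_j = model output` — holds to machine precision on
each model's *raw output scale*: probability for forests (their raw output
is a probability), per-class log-odds margin for boosted models, the
alpha-weighted vote score for SAMME. Multiclass explanations are per-class
matrices. Two registry members have no exact leaf-additive decomposition —
kNN, and AdaBoost.R2 whose weighted median is not a sum over trees — and
use a seeded Monte-Carlo permutation-sampling approximation instead.

Permutation importance is the mean drop in an evaluation score over 5
seeded shuffles per feature (sign flipped for error metrics so larger is
always more important), computed on the model's actual (post-selection)
inputs, by default on the test partition. Note its granularity is bounded
by the metric: F1 on a 40-sample partition moves in steps of 1/40, so weak
importances need a continuous metric (AUC) or pooled partitions to resolve
— the acceptance suite does exactly that.

Exports use the fixed name templates
`permutimp_TopFeatures_info_[Model].csv` and
`shapley_values_all_[Model_Class].csv` (one per class; no class suffix for
regression); the default ranking length is 15 features.

## Synthetic data: what it emulates and what it does not

The generators plant known signal in four families: negative-binomial
counts (log-mean shifts, dispersion 4, baseline mean 100), compositional
Dirichlet-multinomial abundances with log-normal library sizes (so
read-count, abundance and prevalence filters have realistic work),
Hardy-Weinberg genotype dosages (allele-frequency shifts), and Gaussian
tabular data (mean shifts in units of the noise SD). Regression targets are
linear in the informative features with the planted population R²
computable from coefficients and noise; coefficients are drawn from
±Uniform(0.5, 1.5), so the weakest planted features sit near the
detectability boundary at moderate n — deliberately: selection should have
something to get wrong. Class labels are balanced by construction unless a
test unbalances them.

Not emulated: phylogenetic or co-expression correlation structure, batch
effects, nonlinear or interaction effects, label noise. A green end-to-end
test therefore establishes that the machinery recovers *independent,
additive* planted signal — not that any particular biological dataset will
behave as well.

For the end-to-end regression check, sizes are the generator's stated
conditions (n = 500, p = 50, 10 informative, planted R² = 0.8) and the run
is scored by R², the quantity under test. A known limitation, measured
during development and reproducible by changing one argument: at p = 500
the univariate selection stage loses one to two of the weakest planted
features among the null background and the tree registry's test R² drops to
roughly 0.65 — classical tree ensembles on a dense *linear* signal capture
about 85–90% of the explainable variance, and the registry deliberately
contains no linear learner (neural and auto-ensembling backends are out of
scope).

## Numerical and degenerate-input choices

* Binary precision/F1 refer to the positive class, defined as the second
  factor level; multiclass averages are weighted by class support.
* AUC is the rank statistic (average over present classes, one-vs-rest,
  support-weighted); it errors rather than guessing when only one class is
  present or probabilities are missing.
* MAPE errors on any zero observed value; R² errors on a constant target.
* `select_k_best` ties break by input order; infinite scores sort first.
* Stratified splits allocate `round(test_size · n_c)` per class, clamped so
  no class empties; every class needs ≥ 2 members.
* Stage seeds are derived from the run seed by fixed integer mixing
  (`derive_seed`), so stages are reproducible independently of one
  another's draw counts; two runs with the same configuration and seed are
  bit-identical, which the acceptance suite asserts.
* Oversampling keeps every original row and adds sampled exact copies;
  undersampling samples without replacement.

## Run modes and persistence

Training persists a bundle (quantile map, selected features, every tuned
model, the run object, a JSON manifest with seed, config hash and package
version) under the output directory. `holdout` and `predict` replay the
persisted transforms on new tables — they never refit anything — and the
tests assert bit-identical replay of training-time predictions. `plot`
re-renders any subset of the figure list from the bundle; every figure is
written with a companion CSV of exactly the plotted numbers, because plot
*data* is testable and pixels are not.
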