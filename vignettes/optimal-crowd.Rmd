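---
title: "The optimal crowd: methods, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The optimal crowd: methods, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdopt)
```

## The model

`crowdopt` fits a meta-classifier over a researcher-chosen family of `M`
binary machines. Each machine is taught from the training data and emits,
for any point, a class-1 probability that is clipped into [0,1] and
binarized at a 50% cut-point (or a hard label, for pure-class machines).
The joint vector of the `M` binarized predictions indexes a *cell*; the
training outcomes are partitioned across the occupied cells. Prediction
for a test point routes its own joint prediction vector to the nearest
occupied cell(s) under Hamming distance and averages the *known outcomes*
stored there — not the machines' predictions. The averaged probability is
then thresholded at the same 50% cut-point.

Two properties follow directly from the construction:

- **Totality.** Some cell is always occupied (the training data fills at
  least one), so the Hamming fallback guarantees an estimate for every
  possible query vector — there is no empty-cell failure mode. The test
  suite checks this exhaustively against a brute-force scan for `M <= 6`.
- **Partition.** Cell sizes always sum to the training count; this
  conservation is asserted after every fit.

The only substantive assumption the averaging step needs is that the
outcome is bounded — trivially true for 0/1 outcomes. The crowd itself has
no tuning parameters: all modelling freedom (and all model-selection cost)
stays inside the base machines, and the crowd is guaranteed, with enough
data, to do as well as the best of them, whichever that turns out to be.

## Tunable parameters and defaults

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `cutpoint` | `optimal_crowd()` | 0.5 | probability threshold for the final label and for binarizing probability machines |
| `n_trees` | RF specs | 100 | trees per forest |
| `min_leaf_fraction` | RF specs | 0.01 | fraction of training samples required to fill a terminal leaf; the forest's smoothness control |
| `k` | kNN specs | 5 | neighbours (capped at the training size at fit time) |
| `kernel`, `degree` | SVM specs | radial, 3 | kernel family for the margin |
| `syn` | `optimal_crowd()` | `FALSE` | add the synthetic-feature random forest as an `(M+1)`-th member |
| `table_predictions` | `optimal_crowd()` | `"insample"` | how the cell table is keyed (below) |
| `n_per_class`, `delta`, `d` | `gaussian_mixture()` | —, 2, 2 | simulation design (below) |

The stock registries (`crowd_registry(3/10/18)`) span the three families
with the hyperparameters practitioners conventionally vary — RF leaf
fraction, kNN `k`, SVM kernel — and nest (3 ⊂ 10 ⊂ 18). The exact
compositions are a package choice, documented in `?crowd_registry` and
fully replaceable from a YAML file via `crowd_registry_from_file()`: the
method's appeal is precisely that the family can be assembled from
subject-matter preference without a selection step.

## Design choices where the design was open

- **Tie at the cut-point.** A probability of exactly 0.5 is declared
  class 0. Any fixed rule works; an explicit deterministic one is required
  for reproducibility, and strict inequality for class 1 is the
  conservative reading of "exceeds a 50% cut-point".
- **Tied nearest cells are pooled, never sampled.** When several occupied
  cells tie at the minimal Hamming distance, the outcomes of *all* of them
  are averaged. The two-machine fallback geometry (query `(0,1)` pooling
  cells `(0,0)` and `(1,1)`) dictates this.
- **In-sample cell keys by default.** The table is keyed by the machines'
  predictions on the very data they were trained on. This is the plain
  reading of building the table from predictions "on all the training
  data", and it keeps the crowd training-free. Optimistic keying is a real
  possibility (a memorizing member such as 1-NN produces pure cells
  in-sample), so `table_predictions = "out_of_fold"` keys the table with
  5-fold out-of-fold predictions instead; it is a non-default flag because
  the in-sample construction is the documented baseline.
- **How the synthetic machine joins.** With `syn = TRUE` the synthetic
  random forest becomes one additional crowd member — keys grow by one bit
  — and the base machines are *not* refitted on the augmented data. That
  is the minimal reading of "its output was also added"; the maximal
  reading (refit every machine on the augmented features) is available via
  `refit_on_augmented = TRUE`. Test-time synthetic features are the base
  machines' predictions on the test point, so no outcome information can
  leak: the prediction interface accepts no test labels at all.
- **Scaling scope.** Min-max scaling to [0,1] is fitted on the training
  fold only and applied to the held-out fold, so the evaluation data's
  range never influences training; a `scale = "global"` option exists for
  strict-reproduction attempts where a single global scaling is wanted.
  Constant features map to 0; held-out values outside the training range
  are preserved, not clipped.
- **Fold orientation.** `five_fold_cv()` defaults to the standard
  orientation (train on 4/5, test on 1/5). The inverted orientation —
  train on a single fold, evaluate on the rest, so each model sees only
  20% of the data — is available as `invert_folds = TRUE`; both are
  legitimate protocols and neither is asserted as canonical.
- **Machine order.** Cell keys are order-sensitive, so the registry's
  insertion order is fixed and recorded in the model. Predictions are
  invariant to consistent reordering (a tested property).
- **Seeds.** Machine `i` receives `seed + i`; fold assignment, subsampling
  and simulation each consume the seed explicitly. Reports and manifests
  record it.

## Numerical and degenerate-input rules

- Probability outputs are clipped into [0,1] unconditionally before any
  use; SVMs are the family that actually needs it.
- A single-class training outcome yields a constant machine predicting
  that class, rather than an error.
- kNN vote ties (even `k`) are resolved by a seeded draw so prediction is
  deterministic given the fitted machine; distance ties include all tied
  neighbours.
- Nearest-cell search scans the occupied keys (at most `n` of them), never
  the `2^M` hypercube; the exhaustive enumeration exists only as a test
  oracle.
- Labels are canonicalized to 0/1 at ingest (sorted order: smaller label
  maps to 0) and decoded back in every user-facing prediction.

## What the simulator emulates — and what it does not

`gaussian_mixture()` draws equal-prior classes `N(0, I_d)` and
`N(delta·e1, I_d)`. Its virtue is a closed-form optimum:
`bayes_error(delta) = pnorm(-delta/2)`, so simulation studies can measure
distance from the true floor rather than from another estimator. The
package default is `delta = 2`, `d = 2`: a moderate-overlap,
low-dimensional design in which Bayes-consistent members (kNN, radial
SVM) approach the floor at a few thousand samples, which is what the
crowd's "at least as good as the best member, given sufficient data"
guarantee presumes. The optimality experiment
(`optimality_experiment()`, run by the acceptance tests) uses 1000
training samples per class and 20 replicates; its 0.03 comparison margin
is a Monte-Carlo allowance for that replication count, not a substantive
claim.

This generator does **not** emulate real case/control data: features are
independent, Gaussian and equally informative, classes are exactly
balanced, and the decision boundary is linear. Passing the simulation
suite shows the machinery is correct and the optimality property holds in
a controlled design; it says nothing about error rates on correlated,
mixed-scale clinical features. For that, the ingest pipeline runs the same
protocol on UCI-style files; its unit tests use synthetic stand-ins that
mirror only the documented file *structure* (record counts, missing-value
counts, class counts), so they validate the arithmetic of filtering and
subsampling, not real-data performance.

## Known limitations

- Binary outcomes only; the regression-mode crowd over bounded continuous
  outcomes is out of scope, as are multiclass outcomes, distance-weighted
  cells and interval estimates for the cell probabilities.
- With many machines and small data most cells are tiny; the estimate
  then rests on few outcomes. The cell histogram (`plot(model)`,
  `cell_histogram()`) is the diagnostic.
- In-sample keying with memorizing members yields over-pure cells (see
  above); prefer `out_of_fold` keying when a 1-NN-like member is in the
  family and honest in-sample probabilities matter.
- The guarantee of matching the best member is asymptotic; at small `n`
  the crowd can trail the best machine by a finite-sample margin.
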