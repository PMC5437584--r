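# crowdopt

Combining the predictions of several classifiers usually means averaging
them. `crowdopt` implements a different idea — the *optimal crowd* — aimed
at biostatistical case/control prediction problems where many plausible
machines exist and choosing among them is costly: let every machine in a
family predict, use the joint vector of their binarized predictions only to
*route* a test subject to a compartment ("cell") of the training data, and
then average the **known outcomes** in that cell. The machine predictions
themselves are set aside after the routing. The crowd adds no tuning
parameters of its own, and, given sufficient data, its risk is at least as
good as the best machine in the family — it is asymptotically Bayes optimal
whenever any member is.

## The method

Let a family of `M` binary machines be fitted to training data
`(x_i, y_i)`, `y_i ∈ {0,1}`, and let `h(x) ∈ {0,1}^M` be the vector of
their (50%-cut-point binarized) predictions at a point `x`. The training
set is partitioned into cells `C(v) = { i : h(x_i) = v }`, one per
observed joint prediction vector `v`. For a test point `x*`:

1. compute `v* = h(x*)`;
2. find `d* = min { Hamming(v*, v) : C(v) non-empty }` and the set `V*` of
   all occupied cells at distance `d*` (no tie-breaking — ties are pooled);
3. estimate `P(y = 1 | x*) = mean { y_i : i ∈ C(v), v ∈ V* }`;
4. classify as 1 iff the estimate strictly exceeds 0.5 (a tie goes to 0).

When `d* = 0` this is simply the outcome mean of the test point's own
cell; the Hamming fallback guarantees there is never an empty-cell
failure. With synthetic-feature mode (`syn = TRUE`), each machine's
predictions are appended to the feature matrix as new columns, a single
random forest is trained on the augmented data, and that forest joins the
crowd as an `(M+1)`-th member.

## Worked example

The canonical two-machine toy configuration: machines A and B partition
nine training outcomes into four cells, and cell `(0,1)` holds the known
outcomes `0, 0, 0, 1`. A test subject whose machine predictions are
`(0,1)` is routed to that cell:

```r
library(crowdopt)
fx  <- two_machine_fixture()
tab <- build_cell_table(fx$train_predictions, fx$train_outcomes)
str(estimate_probability(fx$test_vector, tab))
#> List of 3
#>  $ prob_class1: num 0.25
#>  $ d_star     : int 0
#>  $ n_pooled   : int 4
```

The crowd estimates probability 3/4 for outcome 0 and 1/4 for outcome 1
(`prob_class1 = 0.25`, averaged over the `n_pooled = 4` known outcomes at
distance `d_star = 0`), so at the 50% cut-point the subject is declared
outcome 0: `classify(0.25)` returns `0`.

A full modelling run on simulated case/control data with the stock
three-machine registry (random forest, 5-nearest-neighbours, radial SVM):

```r
d   <- gaussian_mixture(n_per_class = 200, delta = 2, seed = 1)
fit <- optimal_crowd(d$X, d$y, machines = crowd_registry(3), seed = 1)
fit
#> Optimal crowd classifier
#>   machines: 3
#>   training samples: 400  features: 2
#>   occupied cells: 8 (key length 3 )
#>   cut-point: 0.5

cv <- five_fold_cv(d, crowd_registry(3), syn = TRUE, seed = 1)
cv
#> 5-fold cross-validation (n = 400, seed = 1)
#>       method mean_error     se
#>  rf_leaf0.01     0.1700 0.0140
#>       knn_k5     0.1700 0.0161
#>   svm_radial     0.1675 0.0102
#>        crowd     0.1700 0.0140
#>    crowd_syn     0.1800 0.0122
```

Each row is a method's five-fold mean percent error (misclassified /
total, on held-out folds) with one standard error; here the crowd matches
its best members, all close to the design's Bayes error
`bayes_error(2) = 0.159`. `plot(cv)` draws the error-bar figure and
`plot(fit)` the per-cell histogram of known-outcome counts;
`summary(fit)` lists the largest cells.

Real UCI-style files run through the same pipeline, e.g. the Wisconsin
breast-cancer file (id column dropped, `?` marking missing values, labels
2 = benign / 4 = malignant):

```r
rec <- read_uci_csv("breast-cancer-wisconsin.data", drop_columns = 1,
                    negative_label = 2, positive_label = 4)
ds  <- complete_case_filter(rec)       # 699 records -> 683 complete cases
sub <- balanced_subsample(ds, 200, seed = 1)
five_fold_cv(sub, crowd_registry(18), syn = TRUE, seed = 1)
```

A command-line wrapper over the same functions lives at
`inst/scripts/crowdopt.R` (subcommands `evaluate`, `simulate`, `fit`,
`predict`).

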