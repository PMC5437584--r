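#' Percent error of a classification
#'
#' The number of misclassified samples divided by the total number of
#' samples — the evaluation measure used throughout the benchmark.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Fraction in \[0,1\].
#' @export
percent_error <- function(predicted, truth) {
  if (length(predicted) == 0L) stop("empty prediction vector", call. = FALSE)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth lengths differ", call. = FALSE)
  }
  mean(predicted != truth)
}

# Stratified fold labels: within each class, shuffled indices are dealt
# round-robin, keeping per-fold class balance within one sample.
stratified_folds <- function(y01, k = 5L, seed = 1L) {
  folds <- integer(length(y01))
  with_seed(seed, {
    for (cls in unique(y01)) {
      idx <- which(y01 == cls)
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Balanced stratified five-fold cross-validation of crowd and machines
#'
#' Runs the full benchmarking protocol on a dataset: stratified k-fold
#' split; per fold, features are min-max scaled on the training fold only,
#' every base machine and the crowd (optionally also the synthetic-feature
#' crowd) are fitted on the training fold, and percent error is measured on
#' the held-out fold. Fold errors are averaged and reported with one
#' standard error (sd of fold errors / sqrt(k)).
#'
#' With `invert_folds = TRUE` the orientation flips: each single fold
#' trains and the other k-1 folds evaluate, so each model sees only
#' 1/k of the data — a much harder regime for the base machines.
#'
#' @param ds A [crowd_dataset()] (typically a [balanced_subsample()]).
#' @param machines Registry of [machine_spec()]s; default [crowd_registry(3)].
#' @param syn `FALSE` (default) for the plain crowd only, `TRUE` to also
#'   evaluate the synthetic-feature crowd.
#' @param k Number of folds; default 5.
#' @param seed Integer seed controlling fold assignment and machine fits.
#' @param invert_folds Train on one fold and test on the rest? Default
#'   `FALSE` (standard CV: train on k-1 folds).
#' @param scale `"train"` (default) fits the min-max scaler on the training
#'   fold only; `"global"` fits it once on the full dataset before
#'   splitting (leaks the evaluation fold's range into training).
#' @return Object of class `crowd_cv`: list with `errors` (k x methods
#'   matrix of per-fold percent errors), `mean`, `se`, `folds`, `seed` and
#'   the run settings. Methods are the machines (by name), `"crowd"` and,
#'   when requested, `"crowd_syn"`.
#' @examples
#' d <- gaussian_mixture(n_per_class = 50, delta = 2, seed = 1)
#' cv <- five_fold_cv(d, crowd_registry(3), seed = 1)
#' cv
#' @export
five_fold_cv <- function(ds, machines = crowd_registry(3), syn = FALSE,
                         k = 5L, seed = 1L, invert_folds = FALSE,
                         scale = c("train", "global")) {
  stopifnot(inherits(ds, "crowd_dataset"))
  scale <- match.arg(scale)
  machines <- validate_registry(machines)
  n <- nrow(ds$X)
  if (n < 2L * k) stop("need at least ", 2L * k, " samples for ", k,
                       "-fold CV", call. = FALSE)
  if (min(table(ds$y)) < k) {
    stop("each class needs at least ", k, " members", call. = FALSE)
  }
  folds <- stratified_folds(ds$y, k = k, seed = seed)
  methods <- c(names(machines), "crowd", if (syn) "crowd_syn")
  errors <- matrix(NA_real_, k, length(methods),
                   dimnames = list(NULL, methods))
  global_scaler <- if (scale == "global") min_max_scale(ds$X)$scaler

  for (f in seq_len(k)) {
    train_idx <- if (invert_folds) folds == f else folds != f
    X_tr <- ds$X[train_idx, , drop = FALSE]
    y_tr <- ds$y[train_idx]
    X_te <- ds$X[!train_idx, , drop = FALSE]
    y_te <- ds$y[!train_idx]
    if (scale == "train") {
      sc <- min_max_scale(X_tr)
      X_tr <- sc$train
      X_te <- apply_scaler(sc$scaler, X_te)
    } else {
      X_tr <- apply_scaler(global_scaler, X_tr)
      X_te <- apply_scaler(global_scaler, X_te)
    }
    model <- optimal_crowd(X_tr, y_tr, machines = machines, seed = seed + f)
    for (i in seq_along(model$machines)) {
      mach_lab <- binarize(machine_predict(model$machines[[i]], X_te),
                           model$cutpoint)
      errors[f, i] <- percent_error(mach_lab, y_te)
    }
    errors[f, "crowd"] <- percent_error(predict(model, X_te, type = "label"),
                                        y_te)
    if (syn) {
      syn_model <- optimal_crowd(X_tr, y_tr, machines = machines, syn = TRUE,
                                 seed = seed + f)
      errors[f, "crowd_syn"] <-
        percent_error(predict(syn_model, X_te, type = "label"), y_te)
    }
  }
  structure(list(
    errors = errors,
    mean = colMeans(errors),
    se = apply(errors, 2L, stats::sd) / sqrt(k),
    folds = folds, k = k, seed = as.integer(seed),
    invert_folds = invert_folds, scale = scale, syn = syn,
    n = n
  ), class = "crowd_cv")
}

#' @export
print.crowd_cv <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validation (n = %d, seed = %d%s)\n",
              x$k, x$n, x$seed,
              if (x$invert_folds) ", inverted folds" else ""))
  df <- data.frame(method = names(x$mean),
                   mean_error = round(x$mean, digits),
                   se = round(x$se, digits), row.names = NULL)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Plot cross-validation percent errors with one-standard-error bars
#'
#' @param x A [five_fold_cv()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.crowd_cv <- function(x, ...) {
  m <- x$mean
  se <- x$se
  i <- seq_along(m)
  graphics::plot(i, m, ylim = range(c(m - se, m + se, 0)), xaxt = "n",
                 xlab = "", ylab = "percent error (fraction)",
                 main = sprintf("%d-fold CV percent error", x$k),
                 pch = 19, ...)
  graphics::axis(1, at = i, labels = names(m), las = 2, cex.axis = 0.8)
  graphics::arrows(i, m - se, i, m + se, angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Per-cell counts of known outcomes in a fitted crowd
#'
#' Tabulates, for every occupied cell of the model's table, how many known
#' class-0 and class-1 training outcomes it holds — the cell-count
#' histogram used to inspect how the machines partition the training data.
#'
#' @param model A fitted [optimal_crowd()] model (or a `cell_table`).
#' @return A data frame of class `cell_histogram` with columns `key`,
#'   `n0`, `n1`, `total`, sorted by decreasing total; totals sum to the
#'   training count.
#' @export
cell_histogram <- function(model) {
  table <- if (inherits(model, "optimal_crowd")) model$table else model
  stopifnot(inherits(table, "cell_table"))
  df <- cell_counts(table)
  class(df) <- c("cell_histogram", "data.frame")
  df
}
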