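#' Fit an optimal crowd meta-classifier
#'
#' Fits every base machine in `machines` on the training data, binarizes
#' each machine's predictions on that same training data at the 50%
#' cut-point, and partitions the known outcomes into cells indexed by the
#' joint prediction vector. The resulting model predicts a new point by
#' routing it — via the machines' joint prediction — to the nearest
#' occupied cell(s) under Hamming distance and averaging the known
#' outcomes found there. The crowd itself has no tuning parameters; all
#' modelling choices live in the base machines.
#'
#' With `syn = TRUE`, each machine's in-sample predictions are appended to
#' the feature matrix as synthetic features, a single random forest is
#' trained on the augmented data, and that forest joins the crowd as an
#' extra member: cell keys then have `M + 1` bits. At prediction time the
#' synthetic features for a test point are the base machines' own
#' predictions on it, so test outcomes are never consulted.
#'
#' `table_predictions = "out_of_fold"` builds the cell table from 5-fold
#' out-of-fold machine predictions instead of in-sample ones (the machines
#' themselves are still fitted on the full training data for prediction).
#' In-sample construction is the default.
#'
#' @param x Numeric feature matrix or data frame (one row per sample), or a
#'   formula.
#' @param y Binary outcome: a 0/1 vector, or any two-level factor/character
#'   vector (levels are mapped to 0/1 in sorted order and decoded back in
#'   predictions).
#' @param machines Ordered list of [machine_spec()]s, e.g. from
#'   [crowd_registry()]. The list order fixes the cell-key bit order.
#' @param syn Add the synthetic-feature random forest as an extra crowd
#'   member? Default `FALSE`.
#' @param syn_spec The [machine_spec()] for the synthetic random forest
#'   (must be family `random_forest`).
#' @param refit_on_augmented With `syn = TRUE`, also refit every base
#'   machine on the augmented data and key the cells by the refitted
#'   machines' predictions (an alternative reading of synthetic-feature
#'   augmentation; default `FALSE`).
#' @param cutpoint Probability threshold in (0,1) for the final
#'   classification and for binarizing probability machines; default 0.5.
#' @param table_predictions `"insample"` (default) or `"out_of_fold"`.
#' @param seed Integer; machine `i` is fitted with seed `seed + i` so the
#'   whole fit is reproducible.
#' @param data,formula For the formula method: a model formula and the data
#'   frame holding its variables.
#' @param ... Passed between methods.
#' @return An object of class `optimal_crowd`: a list with the fitted
#'   `machines` (in key order, the synthetic forest last when present), the
#'   cell `table`, `cutpoint`, `label_map`, and fit metadata. Supports
#'   [predict()][predict.optimal_crowd()], `print()`, `summary()` and
#'   `plot()` (cell-count histogram).
#' @examples
#' d <- gaussian_mixture(n_per_class = 60, delta = 2, seed = 1)
#' fit <- optimal_crowd(d$X, d$y, machines = crowd_registry(3), seed = 1)
#' fit
#' head(predict(fit, d$X, type = "prob"))
#' @export
optimal_crowd <- function(x, ...) UseMethod("optimal_crowd")

#' @rdname optimal_crowd
#' @export
optimal_crowd.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  out <- optimal_crowd.default(x, y, ...)
  out$call <- match.call()
  out$terms <- attr(mf, "terms")
  out
}

#' @rdname optimal_crowd
#' @export
optimal_crowd.default <- function(x, y, machines = crowd_registry(3),
                                  syn = FALSE,
                                  syn_spec = machine_spec("syn_rf", "random_forest"),
                                  refit_on_augmented = FALSE,
                                  cutpoint = 0.5,
                                  table_predictions = c("insample", "out_of_fold"),
                                  seed = 1L, ...) {
  table_predictions <- match.arg(table_predictions)
  x <- as_feature_matrix(x)
  if (nrow(x) < 1L) stop("training data is empty", call. = FALSE)
  lab <- encode_labels(y)
  y01 <- lab$y
  stopifnot(cutpoint > 0, cutpoint < 1)
  machines <- validate_registry(machines)
  M <- length(machines)

  fitted <- vector("list", M)
  for (i in seq_len(M)) {
    fitted[[i]] <- tryCatch(
      fit_machine(machines[[i]], x, y01, seed = seed + i),
      error = function(e) stop("machine '", machines[[i]]$name,
                               "' failed to fit: ", conditionMessage(e),
                               call. = FALSE))
  }
  names(fitted) <- names(machines)

  # n x M probability-scale predictions used to key the cell table
  key_probs <- if (table_predictions == "insample") {
    vapply(fitted, machine_predict, numeric(nrow(x)), newdata = x)
  } else {
    out_of_fold_probs(machines, x, y01, seed)
  }
  key_probs <- matrix(key_probs, nrow = nrow(x))

  syn_rf <- NULL
  refitted <- NULL
  if (syn) {
    stopifnot(syn_spec$family == "random_forest")
    # synthetic features are always the in-sample machine predictions
    aug_cols <- matrix(vapply(fitted, machine_predict, numeric(nrow(x)),
                              newdata = x), nrow = nrow(x))
    x_aug <- augment_with_predictions(x, fitted, pred_cols = aug_cols)
    syn_rf <- fit_machine(syn_spec, x_aug, y01, seed = seed + M + 1L)
    if (refit_on_augmented) {
      refitted <- lapply(seq_len(M), function(i) {
        fit_machine(machines[[i]], x_aug, y01, seed = seed + i)
      })
      names(refitted) <- names(machines)
      key_probs <- matrix(vapply(refitted, machine_predict, numeric(nrow(x)),
                                 newdata = x_aug), nrow = nrow(x))
    }
    key_probs <- cbind(key_probs, machine_predict(syn_rf, x_aug))
  }

  bits <- matrix(binarize(as.vector(key_probs), cutpoint), nrow = nrow(x))
  table <- build_cell_table(bits, y01)

  structure(list(
    machines = fitted, syn_rf = syn_rf, refitted = refitted,
    table = table, cutpoint = cutpoint, label_map = lab$map,
    syn = syn, refit_on_augmented = refit_on_augmented,
    table_predictions = table_predictions,
    p = ncol(x), n_train = nrow(x), seed = as.integer(seed),
    call = match.call()
  ), class = "optimal_crowd")
}

# Map an arbitrary two-level outcome to 0/1; keep the decoding map.
encode_labels <- function(y) {
  if (is.numeric(y) && all(y %in% c(0, 1))) {
    return(list(y = as.integer(y), map = c(`0` = 0L, `1` = 1L)))
  }
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L) {
    stop("outcome must have exactly two distinct values, got ",
         length(lev), call. = FALSE)
  }
  list(y = as.integer(as.character(y) == lev[2L]),
       map = stats::setNames(c(0L, 1L), lev))
}

decode_labels <- function(lab01, map) {
  orig <- names(map)[match(lab01, map)]
  if (identical(names(map), c("0", "1"))) as.integer(orig) else orig
}

validate_registry <- function(machines) {
  if (inherits(machines, "machine_spec")) machines <- list(machines)
  stopifnot(length(machines) >= 1L,
            all(vapply(machines, inherits, TRUE, "machine_spec")))
  nms <- vapply(machines, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("machine names must be unique", call. = FALSE)
  stats::setNames(machines, nms)
}

# 5-fold out-of-fold probability predictions for cell-table construction.
out_of_fold_probs <- function(specs, x, y01, seed) {
  n <- nrow(x)
  folds <- stratified_folds(y01, k = 5L, seed = seed)
  probs <- matrix(NA_real_, n, length(specs))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    for (i in seq_along(specs)) {
      fm <- fit_machine(specs[[i]], x[!hold, , drop = FALSE], y01[!hold],
                        seed = seed + i)
      probs[hold, i] <- machine_predict(fm, x[hold, , drop = FALSE])
    }
  }
  probs
}

#' Predict method for optimal crowd models
#'
#' Computes each machine's binarized prediction for every row of `newdata`,
#' routes the resulting joint prediction vector to the nearest occupied
#' cell(s) of the training table, and averages the known outcomes there.
#'
#' @param object A fitted [optimal_crowd()] model.
#' @param newdata Feature matrix with the fit-time column count.
#' @param type `"label"` (default) for hard classifications on the original
#'   label scale, `"prob"` for the estimated class-1 probability, or
#'   `"full"` for a data frame with `prob_class1`, `label`, `d_star` (the
#'   Hamming distance of the pooled cells; 0 when the point's own cell is
#'   occupied) and `n_pooled` (how many known outcomes were averaged).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.optimal_crowd <- function(object, newdata,
                                  type = c("label", "prob", "full"), ...) {
  type <- match.arg(type)
  newdata <- as_feature_matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop("newdata has ", ncol(newdata), " columns; model was fitted on ",
         object$p, call. = FALSE)
  }
  m <- nrow(newdata)
  base_probs <- matrix(vapply(object$machines, machine_predict, numeric(m),
                              newdata = newdata), nrow = m)
  key_probs <- base_probs
  if (object$syn) {
    x_aug <- augment_with_predictions(newdata, object$machines,
                                      pred_cols = base_probs)
    if (!is.null(object$refitted)) {
      key_probs <- matrix(vapply(object$refitted, machine_predict, numeric(m),
                                 newdata = x_aug), nrow = m)
    }
    key_probs <- cbind(key_probs, machine_predict(object$syn_rf, x_aug))
  }
  bits <- matrix(binarize(as.vector(key_probs), object$cutpoint), nrow = m)

  est <- lapply(seq_len(m), function(i) estimate_probability(bits[i, ], object$table))
  prob <- vapply(est, `[[`, 0, "prob_class1")
  lab01 <- classify(prob, object$cutpoint)
  switch(type,
    prob = prob,
    label = decode_labels(lab01, object$label_map),
    full = data.frame(
      prob_class1 = prob,
      label = decode_labels(lab01, object$label_map),
      d_star = vapply(est, `[[`, 0L, "d_star"),
      n_pooled = vapply(est, `[[`, 0L, "n_pooled")
    )
  )
}

#' @export
print.optimal_crowd <- function(x, ...) {
  cat("Optimal crowd classifier\n")
  cat("  machines: ", length(x$machines),
      if (x$syn) " + 1 synthetic random forest" else "", "\n", sep = "")
  cat("  training samples:", x$n_train, " features:", x$p, "\n")
  cat("  occupied cells:", length(x$table$keys),
      "(key length", x$table$M, ")\n")
  cat("  cut-point:", x$cutpoint, "\n")
  invisible(x)
}

#' @export
summary.optimal_crowd <- function(object, ...) {
  counts <- cell_counts(object$table)
  pure <- mean(counts$n0 == 0 | counts$n1 == 0)
  structure(list(model = object, cells = counts, frac_pure = pure),
            class = "summary.optimal_crowd")
}

#' @export
print.summary.optimal_crowd <- function(x, ...) {
  print(x$model)
  cat("  pure cells:", sprintf("%.0f%%", 100 * x$frac_pure), "\n")
  cat("\nLargest cells (known-outcome counts):\n")
  print(utils::head(x$cells, 10L), row.names = FALSE)
  invisible(x)
}

#' @describeIn cell_histogram Plot method: barplot of per-cell totals.
#' @param x A `cell_histogram`.
#' @export
plot.cell_histogram <- function(x, ...) {
  graphics::barplot(x$total, names.arg = x$key, las = 2,
                    xlab = "cell (joint prediction vector)",
                    ylab = "known outcomes in cell",
                    main = "Cell counts of known outcomes", ...)
  invisible(x)
}

#' Plot an optimal crowd model (cell-count histogram)
#'
#' @param x A fitted [optimal_crowd()] model.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.optimal_crowd <- function(x, ...) {
  plot(cell_histogram(x), ...)
}

#' Save / load a fitted crowd model
#'
#' The model archive holds the fitted machines, the cell table and all
#' metadata (machine order, cut-point, label map) in one file.
#'
#' @param model A fitted [optimal_crowd()] model.
#' @param path File path for the archive.
#' @return `crowd_save` returns `path` invisibly; `crowd_load` returns the
#'   restored model.
#' @export
crowd_save <- function(model, path) {
  stopifnot(inherits(model, "optimal_crowd"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname crowd_save
#' @export
crowd_load <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "optimal_crowd")) {
    stop("file does not contain an optimal_crowd model: ", path, call. = FALSE)
  }
  model
}
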