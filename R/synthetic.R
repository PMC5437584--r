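#' Append machine predictions to a feature matrix as synthetic features
#'
#' Each fitted machine contributes one new column — its predictions on `x`,
#' on the probability scale in \[0,1\] — appended after the original
#' columns in machine order. The original columns are unchanged. The
#' appended columns carry the machines' names prefixed with `"syn_"` so
#' their provenance is readable from the matrix header.
#'
#' @param x Feature matrix (n x p) compatible with the machines' fit-time
#'   feature space.
#' @param fitted_machines Ordered list of [fit_machine()] results.
#' @param pred_cols Optional precomputed n x M prediction matrix (one
#'   column per machine, in machine order); when supplied it is appended
#'   as-is instead of recomputing predictions.
#' @return An n x (p + M) matrix.
#' @export
augment_with_predictions <- function(x, fitted_machines, pred_cols = NULL) {
  x <- as_feature_matrix(x)
  stopifnot(all(vapply(fitted_machines, inherits, TRUE, "fitted_machine")))
  if (is.null(pred_cols)) {
    pred_cols <- matrix(vapply(fitted_machines, machine_predict,
                               numeric(nrow(x)), newdata = x),
                        nrow = nrow(x))
  }
  stopifnot(nrow(pred_cols) == nrow(x),
            ncol(pred_cols) == length(fitted_machines))
  nms <- vapply(fitted_machines, function(m) m$spec$name, "")
  colnames(pred_cols) <- paste0("syn_", nms)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  cbind(x, pred_cols)
}

#' Train the synthetic random forest on an augmented matrix
#'
#' Fits a single random forest on the feature matrix already augmented
#' with the base machines' prediction columns, and appends that forest's
#' own in-sample predictions as one further column. The returned forest is
#' the extra crowd member used by `optimal_crowd(..., syn = TRUE)`.
#'
#' @param x_aug Augmented matrix from [augment_with_predictions()].
#' @param y Binary 0/1 outcomes.
#' @param rf_spec A `random_forest` [machine_spec()].
#' @param seed Integer seed.
#' @return A list with `machine` (the fitted forest) and `x_aug` (the input
#'   with the forest's prediction column appended as `syn_rf_out`).
#' @export
add_synthetic_rf <- function(x_aug, y,
                             rf_spec = machine_spec("syn_rf", "random_forest"),
                             seed = 1L) {
  stopifnot(rf_spec$family == "random_forest")
  fm <- fit_machine(rf_spec, x_aug, y, seed = seed)
  out <- cbind(x_aug, syn_rf_out = machine_predict(fm, x_aug))
  list(machine = fm, x_aug = out)
}
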