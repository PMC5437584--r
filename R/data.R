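#' Read a UCI-style delimited classification file
#'
#' Reads comma-separated records with numeric feature columns and one class
#' column, the common layout of UCI machine-learning repository `.data`
#' files. Missing feature values marked by `missing_token` (or empty
#' fields) become `NA` and flag the row; class labels are mapped to 0/1.
#'
#' @param path Path to the delimited file (no header unless `header`).
#' @param missing_token Token marking a missing feature value; default `"?"`.
#' @param label_column Index of the class column; default the last column.
#' @param positive_label,negative_label The original label values mapping
#'   to 1 and 0. When omitted, the two distinct label values found are used
#'   in sorted order (smaller to 0). Any label outside the pair is an error.
#' @param drop_columns Column indices to discard before use (e.g. a sample
#'   id column); default none.
#' @param sep Field separator; default comma.
#' @param header Does the file carry a header line? Default `FALSE`.
#' @return An object of class `uci_records`: a list with `X` (numeric
#'   matrix, `NA` where missing), `y` (0/1 integer), `missing` (logical
#'   per-row flag), `label_map` and `feature_names`.
#' @seealso [complete_case_filter()] to drop flagged rows.
#' @export
read_uci_csv <- function(path, missing_token = "?", label_column = NULL,
                         positive_label = NULL, negative_label = NULL,
                         drop_columns = integer(), sep = ",", header = FALSE) {
  raw <- utils::read.table(path, sep = sep, header = header,
                           na.strings = c(missing_token, ""),
                           colClasses = "character",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (length(drop_columns)) raw <- raw[, -drop_columns, drop = FALSE]
  if (is.null(label_column)) label_column <- ncol(raw)
  y_raw <- raw[[label_column]]
  feats <- raw[, -label_column, drop = FALSE]

  X <- suppressWarnings(vapply(feats, as.numeric, numeric(nrow(feats))))
  X <- matrix(X, nrow = nrow(feats),
              dimnames = list(NULL, colnames(feats)))
  bad <- which(!is.na(as.matrix(feats)) & is.na(X), arr.ind = TRUE)
  if (nrow(bad <- unique(bad)) > 0) {
    stop("non-numeric feature value(s) at line(s) ",
         paste(utils::head(sort(unique(bad[, 1])) + header, 10), collapse = ", "),
         call. = FALSE)
  }

  if (anyNA(y_raw)) {
    stop("missing class label at line(s) ",
         paste(utils::head(which(is.na(y_raw)) + header, 10), collapse = ", "),
         call. = FALSE)
  }
  lev <- sort(unique(y_raw))
  if (is.null(positive_label) && is.null(negative_label)) {
    if (length(lev) != 2L) {
      stop("expected exactly 2 class labels, found: ",
           paste(lev, collapse = ", "), call. = FALSE)
    }
    negative_label <- lev[1L]
    positive_label <- lev[2L]
  } else {
    known <- c(negative_label, positive_label)
    unknown <- setdiff(lev, as.character(known))
    if (length(unknown)) {
      stop("unknown class label value(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(
    X = X,
    y = as.integer(y_raw == as.character(positive_label)),
    missing = rowSums(is.na(X)) > 0L,
    label_map = stats::setNames(c(0L, 1L),
                                c(as.character(negative_label),
                                  as.character(positive_label))),
    feature_names = colnames(X)
  ), class = "uci_records")
}

#' Keep only complete cases
#'
#' Drops every record flagged as having a missing feature value and
#' returns a clean dataset. The number of removed rows is reported via
#' a message and the `"n_removed"` attribute.
#'
#' @param records A [read_uci_csv()] result.
#' @return A `crowd_dataset` (list with `X`, `y`, `feature_names`,
#'   `label_map`).
#' @export
complete_case_filter <- function(records) {
  stopifnot(inherits(records, "uci_records"))
  keep <- !records$missing
  if (!any(keep)) stop("no complete cases remain after filtering", call. = FALSE)
  n_removed <- sum(!keep)
  message(n_removed, " record(s) with missing values removed; ",
          sum(keep), " retained")
  ds <- crowd_dataset(records$X[keep, , drop = FALSE], records$y[keep],
                      feature_names = records$feature_names,
                      label_map = records$label_map)
  attr(ds, "n_removed") <- n_removed
  ds
}

#' Construct a classification dataset container
#'
#' @param X Numeric feature matrix without missing values.
#' @param y Binary 0/1 outcomes (or a two-level vector, encoded on entry).
#' @param feature_names Optional column names.
#' @param label_map Named 0/1 integer vector mapping original labels.
#' @return Object of class `crowd_dataset`.
#' @export
crowd_dataset <- function(X, y, feature_names = colnames(X), label_map = NULL) {
  X <- as_feature_matrix(X)
  lab <- encode_labels(y)
  if (is.null(label_map)) label_map <- lab$map
  if (!is.null(feature_names)) colnames(X) <- feature_names
  structure(list(X = X, y = lab$y, feature_names = colnames(X),
                 label_map = label_map),
            class = "crowd_dataset")
}

#' @export
print.crowd_dataset <- function(x, ...) {
  cat("<crowd_dataset> ", nrow(x$X), " samples, ", ncol(x$X), " features; ",
      "class counts 0/1: ", sum(x$y == 0), "/", sum(x$y == 1), "\n", sep = "")
  invisible(x)
}

#' Min-max scale features to the unit interval
#'
#' Computes a per-feature affine map from the training data only — so no
#' information leaks from evaluation data into the scaling — and applies it
#' to the training set and to any further datasets. Training features land
#' in \[0,1\]; a constant training feature maps to 0. Values of other
#' datasets falling outside the training range are preserved as-is (they
#' may leave \[0,1\]), not clipped.
#'
#' @param train A `crowd_dataset` or numeric matrix defining the map.
#' @param others List of further datasets/matrices to transform with the
#'   training map.
#' @return List with `train` (scaled), `others` (list, scaled) and
#'   `scaler` (list of per-feature `min` and `range`, reusable via
#'   [apply_scaler()]).
#' @export
min_max_scale <- function(train, others = list()) {
  Xtr <- if (inherits(train, "crowd_dataset")) train$X else as_feature_matrix(train)
  mins <- apply(Xtr, 2L, min)
  ranges <- apply(Xtr, 2L, max) - mins
  scaler <- list(min = mins, range = ranges)
  rescale <- function(d) apply_scaler(scaler, d)
  list(train = rescale(train), others = lapply(others, rescale), scaler = scaler)
}

#' @rdname min_max_scale
#' @param scaler The `scaler` component of a [min_max_scale()] result.
#' @param data A `crowd_dataset` or matrix to transform.
#' @export
apply_scaler <- function(scaler, data) {
  is_ds <- inherits(data, "crowd_dataset")
  X <- if (is_ds) data$X else as_feature_matrix(data)
  stopifnot(ncol(X) == length(scaler$min))
  rng <- ifelse(scaler$range == 0, 1, scaler$range) # constant feature -> 0
  Xs <- sweep(sweep(X, 2L, scaler$min, "-"), 2L, rng, "/")
  Xs[, scaler$range == 0] <- 0
  if (is_ds) { data$X <- Xs; data } else Xs
}

#' Balanced subsample of a dataset
#'
#' Draws exactly `n_per_class` members of each class, without replacement,
#' deterministically for a given seed — the balanced pools used for
#' cross-validation benchmarking.
#'
#' @param ds A `crowd_dataset`.
#' @param n_per_class Samples to draw from each class.
#' @param seed Integer seed.
#' @return A `crowd_dataset` with `2 * n_per_class` rows (class-0 block
#'   first).
#' @export
balanced_subsample <- function(ds, n_per_class, seed = 1L) {
  stopifnot(inherits(ds, "crowd_dataset"))
  idx0 <- which(ds$y == 0L)
  idx1 <- which(ds$y == 1L)
  if (length(idx0) < n_per_class || length(idx1) < n_per_class) {
    stop("a class has fewer than ", n_per_class, " members (",
         length(idx0), "/", length(idx1), ")", call. = FALSE)
  }
  pick <- with_seed(seed, c(sample(idx0, n_per_class), sample(idx1, n_per_class)))
  crowd_dataset(ds$X[pick, , drop = FALSE], ds$y[pick],
                feature_names = ds$feature_names, label_map = ds$label_map)
}
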