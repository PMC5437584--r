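#' Hamming distance between two binary prediction vectors
#'
#' The number of positions at which two equal-length 0/1 vectors differ.
#' This is the measure of closeness used when a test point's own cell is
#' empty and the crowd must fall back to the nearest occupied cells.
#'
#' @param u,v Binary (0/1) vectors of equal length.
#' @return A non-negative integer count of mismatched positions.
#' @examples
#' hamming_distance(c(0, 1), c(1, 0)) # 2
#' hamming_distance(c(0, 1), c(0, 1)) # 0
#' @export
hamming_distance <- function(u, v) {
  u <- check_binary(u, "prediction vector u")
  v <- check_binary(v, "prediction vector v")
  if (length(u) != length(v)) {
    stop("prediction vectors have different lengths (", length(u), " vs ",
         length(v), ")", call. = FALSE)
  }
  sum(u != v)
}

# Encode rows of a binary matrix as cell-key strings, e.g. "01".
cell_key <- function(bits) {
  if (is.matrix(bits)) apply(bits, 1L, paste0, collapse = "") else paste0(bits, collapse = "")
}

# Decode a key string back to an integer bit vector.
key_bits <- function(key) as.integer(strsplit(key, "", fixed = TRUE)[[1L]])

#' Build the cell table from machine predictions and known outcomes
#'
#' Partitions the training outcomes into cells indexed by the joint
#' prediction vector of the machines: row i of `predictions` is the key of
#' the cell that receives `outcomes[i]`. Only occupied cells are stored, so
#' every stored cell is non-empty and cell sizes sum to the training count.
#'
#' @param predictions An n x M binary matrix; column j holds machine j's
#'   binarized predictions on the training data.
#' @param outcomes Length-n binary vector of known training outcomes.
#' @return An object of class `cell_table` with fields `keys` (occupied
#'   cell keys), `key_matrix` (their bit rows), `outcomes` (list of outcome
#'   vectors, one per occupied cell), `n_train` and `M`.
#' @examples
#' tab <- build_cell_table(matrix(c(0, 1), 4, 2, byrow = TRUE), c(0, 0, 0, 1))
#' tab$outcomes[["01"]] # all four outcomes share the (0,1) cell
#' @export
build_cell_table <- function(predictions, outcomes) {
  if (is.vector(predictions)) predictions <- matrix(predictions, nrow = 1L)
  predictions <- as.matrix(predictions)
  n <- nrow(predictions)
  if (n == 0L) stop("cannot build a cell table from empty training data", call. = FALSE)
  storage.mode(predictions) <- "integer"
  if (anyNA(predictions) || !all(predictions %in% c(0L, 1L))) {
    stop("predictions must contain only 0 and 1", call. = FALSE)
  }
  outcomes <- check_binary(outcomes, "outcomes")
  if (length(outcomes) != n) {
    stop("predictions have ", n, " rows but there are ", length(outcomes),
         " outcomes", call. = FALSE)
  }
  keys_all <- cell_key(predictions)
  groups <- split(outcomes, keys_all)
  keys <- names(groups)
  key_matrix <- do.call(rbind, lapply(keys, key_bits))
  structure(
    list(keys = keys, key_matrix = key_matrix, outcomes = groups,
         n_train = n, M = ncol(predictions)),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat("Cell table: ", length(x$keys), " occupied cell(s) over ", x$M,
      " machine(s), ", x$n_train, " training outcomes\n", sep = "")
  invisible(x)
}

#' Find all occupied cells nearest to a query prediction vector
#'
#' Computes the minimal Hamming distance `d_star` from the query to any
#' occupied cell and returns every occupied cell at exactly that distance.
#' No tie-breaking is applied: ties are resolved later by pooling the
#' outcomes of all returned cells.
#'
#' @param query Binary vector of length `table$M`.
#' @param table A [build_cell_table()] result.
#' @return A list with `d_star` (integer) and `keys` (character vector of
#'   all occupied cell keys at distance `d_star`).
#' @examples
#' tab <- build_cell_table(rbind(c(0, 0), c(1, 1)), c(0, 1))
#' nearest_cells(c(0, 1), tab) # d_star = 1, both cells tie
#' @export
nearest_cells <- function(query, table) {
  stopifnot(inherits(table, "cell_table"))
  if (length(table$keys) == 0L) stop("cell table has no occupied cells", call. = FALSE)
  query <- check_binary(query, "query")
  if (length(query) != table$M) {
    stop("query has length ", length(query), " but the table was built over ",
         table$M, " machines", call. = FALSE)
  }
  d <- as.integer(table$key_matrix %*% (1L - 2L * query)) + sum(query)
  d_star <- min(d)
  list(d_star = d_star, keys = table$keys[d == d_star])
}

#' Estimate the class-1 probability for a query prediction vector
#'
#' Pools the known training outcomes of every occupied cell at minimal
#' Hamming distance from the query and returns their mean. Because some
#' cell is always occupied, the estimate is always defined: there is no
#' empty-cell failure mode.
#'
#' @inheritParams nearest_cells
#' @return A list with `prob_class1` (mean pooled outcome, in \[0,1\]),
#'   `d_star` (distance of the pooled cells) and `n_pooled` (number of
#'   known outcomes averaged, at least 1).
#' @examples
#' tab <- build_cell_table(matrix(c(0, 1), 4, 2, byrow = TRUE), c(0, 0, 0, 1))
#' estimate_probability(c(0, 1), tab) # 1/4 for class 1
#' @export
estimate_probability <- function(query, table) {
  nc <- nearest_cells(query, table)
  pooled <- unlist(table$outcomes[nc$keys], use.names = FALSE)
  list(prob_class1 = mean(pooled), d_star = nc$d_star, n_pooled = length(pooled))
}

#' Convert an estimated probability to a 0/1 label at a cut-point
#'
#' Declares class 1 only when the probability strictly exceeds the
#' cut-point; an exact tie is declared class 0. The deterministic tie rule
#' makes runs reproducible.
#'
#' @param prob_class1 Probability (or vector of probabilities) in \[0,1\].
#' @param cutpoint Threshold in (0,1); default 0.5, the 50% cut-point.
#' @return Integer label(s) 0 or 1.
#' @examples
#' classify(0.25) # 0
#' classify(0.5)  # 0 (tie rule)
#' @export
classify <- function(prob_class1, cutpoint = 0.5) {
  if (anyNA(prob_class1) || any(prob_class1 < 0) || any(prob_class1 > 1)) {
    stop("probabilities must lie in [0,1]", call. = FALSE)
  }
  stopifnot(cutpoint > 0, cutpoint < 1)
  as.integer(prob_class1 > cutpoint)
}

#' Export a cell table as delimited text
#'
#' Writes one row per occupied cell: the key bits (one column per machine),
#' the count of known 0 outcomes and the count of known 1 outcomes.
#'
#' @param table A [build_cell_table()] result or a fitted [optimal_crowd()]
#'   model (its table is used).
#' @param path Output file path (tab-separated, with header).
#' @return The exported data frame, invisibly.
#' @export
export_cell_table <- function(table, path) {
  if (inherits(table, "optimal_crowd")) table <- table$table
  stopifnot(inherits(table, "cell_table"))
  df <- cell_counts(table)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

# Per-cell 0/1 outcome counts as a data frame, sorted by total size.
cell_counts <- function(table) {
  n1 <- vapply(table$outcomes, sum, integer(1))
  n_tot <- lengths(table$outcomes)
  df <- data.frame(key = names(table$outcomes), n0 = n_tot - n1, n1 = n1,
                   total = n_tot, row.names = NULL, stringsAsFactors = FALSE)
  df[order(-df$total, df$key), , drop = FALSE]
}
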