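#' Stock registries of 3, 10 or 18 base machines
#'
#' Returns an ordered list of [machine_spec()]s spanning the random forest,
#' k-nearest-neighbour and SVM families. The compositions are the package's
#' documented defaults — chosen to span the families and the hyperparameters
#' that are conventionally varied (RF terminal-leaf fraction, kNN `k`, SVM
#' kernel) — and the registries nest: every size-3 machine is in the size-10
#' registry, and every size-10 machine in the size-18 one. Anyone with
#' better information can replace them wholesale via
#' [crowd_registry_from_file()].
#'
#' \describe{
#'   \item{size 3}{RF(100 trees, leaf fraction 0.01), kNN(k=5), SVM(radial).}
#'   \item{size 10}{RF leaf fraction in 0.01/0.05/0.10; kNN k in
#'     1/3/5/9/15; SVM radial and linear.}
#'   \item{size 18}{RF leaf fraction in 0.01/0.02/0.05/0.10/0.15/0.25; kNN
#'     k in 1/3/5/7/9/15/21; SVM radial, linear, polynomial (degree 2 and
#'     3) and sigmoid.}
#' }
#'
#' @param size One of 3, 10, 18.
#' @param mode Output mode applied to every spec: `"probability"` (default)
#'   or `"pure_class"`.
#' @return Ordered list of `size` distinct `machine_spec`s; the order is
#'   deterministic and defines the cell-key bit order.
#' @examples
#' names(crowd_registry(3)) # rf_leaf0.01, knn_k5, svm_radial
#' @export
crowd_registry <- function(size = 3, mode = c("probability", "pure_class")) {
  mode <- match.arg(mode)
  if (!size %in% c(3, 10, 18)) {
    stop("supported registry sizes are 3, 10 and 18", call. = FALSE)
  }
  rf_fracs <- switch(as.character(size),
    "3" = 0.01, "10" = c(0.01, 0.05, 0.10),
    "18" = c(0.01, 0.02, 0.05, 0.10, 0.15, 0.25))
  knn_ks <- switch(as.character(size),
    "3" = 5L, "10" = c(1L, 3L, 5L, 9L, 15L),
    "18" = c(1L, 3L, 5L, 7L, 9L, 15L, 21L))
  svms <- switch(as.character(size),
    "3" = list(list(kernel = "radial")),
    "10" = list(list(kernel = "radial"), list(kernel = "linear")),
    "18" = list(list(kernel = "radial"), list(kernel = "linear"),
                list(kernel = "polynomial", degree = 3L),
                list(kernel = "polynomial", degree = 2L),
                list(kernel = "sigmoid")))
  specs <- c(
    lapply(rf_fracs, function(f) {
      machine_spec(sprintf("rf_leaf%.2f", f), "random_forest",
                   n_trees = 100L, min_leaf_fraction = f, mode = mode)
    }),
    lapply(knn_ks, function(k) {
      machine_spec(sprintf("knn_k%d", k), "knn", k = k, mode = mode)
    }),
    lapply(svms, function(s) {
      nm <- if (s$kernel == "polynomial") sprintf("svm_poly%d", s$degree)
            else paste0("svm_", s$kernel)
      do.call(machine_spec, c(list(nm, "svm", mode = mode), s))
    })
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Read a machine registry from a YAML config file
#'
#' The file holds a list of machine entries, each with `name`, `family`,
#' optional `mode` and family hyperparameters, e.g.:
#' ```yaml
#' - name: rf_small
#'   family: random_forest
#'   n_trees: 100
#'   min_leaf_fraction: 0.05
#' - name: knn7
#'   family: knn
#'   k: 7
#'   mode: pure_class
#' ```
#'
#' @param path Path to the YAML file.
#' @return Ordered named list of [machine_spec()]s, in file order.
#' @export
crowd_registry_from_file <- function(path) {
  entries <- yaml::read_yaml(path)
  if (!length(entries)) stop("registry config is empty: ", path, call. = FALSE)
  specs <- lapply(entries, function(e) {
    if (is.null(e$name) || is.null(e$family)) {
      stop("each registry entry needs 'name' and 'family'", call. = FALSE)
    }
    hp <- e[setdiff(names(e), c("name", "family", "mode"))]
    do.call(machine_spec,
            c(list(name = e$name, family = e$family), hp,
              list(mode = if (is.null(e$mode)) "probability" else e$mode)))
  })
  nms <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("machine names must be unique", call. = FALSE)
  stats::setNames(specs, nms)
}
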