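#' Clip a probability-like value into the unit interval
#'
#' Support vector machines (and other probability machines) can emit
#' "probabilities" outside \[0,1\]. The rule applied throughout the package
#' is the simple one: values above 1 map to 1 and values below 0 map to 0.
#'
#' @param p Finite numeric vector.
#' @return `pmin(1, pmax(0, p))`.
#' @examples
#' clip_probability(c(1.3, -0.2, 0.6)) # 1, 0, 0.6
#' @export
clip_probability <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p))) {
    stop("probabilities must be finite numbers", call. = FALSE)
  }
  pmin(1, pmax(0, p))
}

#' Binarize a probability at a cut-point
#'
#' Converts a probability-machine output to a hard 0/1 prediction using the
#' same strict-inequality rule as [classify()]: 1 only when `p > cutpoint`,
#' an exact tie giving 0.
#'
#' @param p Probabilities in \[0,1\] (clip first if necessary).
#' @param cutpoint Threshold, default 0.5.
#' @return Integer 0/1 vector.
#' @export
binarize <- function(p, cutpoint = 0.5) {
  if (any(p < 0) || any(p > 1)) stop("p must lie in [0,1]; clip first", call. = FALSE)
  as.integer(p > cutpoint)
}

#' Declare one base machine of the crowd
#'
#' A machine spec names a family, its hyperparameters and its output mode.
#' Supported families and hyperparameters:
#' \describe{
#'   \item{`random_forest`}{`n_trees` (default 100) and `min_leaf_fraction`,
#'     the fraction of training samples required to fill a terminal leaf
#'     node (default 0.01).}
#'   \item{`knn`}{`k`, the number of neighbours (default 5; capped at the
#'     training size at fit time).}
#'   \item{`svm`}{`kernel` in radial/linear/polynomial/sigmoid, plus
#'     `degree` for polynomial kernels (default 3).}
#' }
#' `mode = "probability"` machines emit a class-1 probability (clipped to
#' \[0,1\], binarized at 50% before entering the crowd); `mode =
#' "pure_class"` machines emit hard 0/1 labels directly.
#'
#' @param name Unique identifier within a registry.
#' @param family One of `"random_forest"`, `"knn"`, `"svm"`.
#' @param ... Family hyperparameters (see above).
#' @param mode `"probability"` or `"pure_class"`.
#' @return An object of class `machine_spec`.
#' @examples
#' machine_spec("rf_a", "random_forest", n_trees = 100, min_leaf_fraction = 0.01)
#' @export
machine_spec <- function(name, family = c("random_forest", "knn", "svm"),
                         ..., mode = c("probability", "pure_class")) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  hp <- list(...)
  defaults <- switch(family,
    random_forest = list(n_trees = 100L, min_leaf_fraction = 0.01),
    knn = list(k = 5L),
    svm = list(kernel = "radial", degree = 3L)
  )
  unknown <- setdiff(names(hp), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameter(s) for family '", family, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hp <- utils::modifyList(defaults, hp)
  if (family == "svm") {
    hp$kernel <- match.arg(hp$kernel, c("radial", "linear", "polynomial", "sigmoid"))
  }
  if (family == "knn" && (hp$k < 1 || hp$k != round(hp$k))) {
    stop("k must be a positive integer", call. = FALSE)
  }
  if (family == "random_forest" &&
      (hp$min_leaf_fraction <= 0 || hp$min_leaf_fraction >= 1)) {
    stop("min_leaf_fraction must lie in (0,1)", call. = FALSE)
  }
  structure(list(name = as.character(name), family = family,
                 hyperparams = hp, mode = mode),
            class = "machine_spec")
}

#' @export
print.machine_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparams), unlist(x$hyperparams), sep = "=", collapse = ", ")
  cat(sprintf("<machine_spec> %s: %s(%s), mode=%s\n", x$name, x$family, hp, x$mode))
  invisible(x)
}

#' Fit one base machine
#'
#' Trains the machine described by `spec` on `(x, y)`. Fitting is
#' deterministic given `(spec, x, y, seed)`; the caller's RNG state is left
#' untouched. If `y` contains a single class the result is a constant
#' machine predicting that class.
#'
#' @param spec A [machine_spec()].
#' @param x Numeric feature matrix (n x p).
#' @param y Binary 0/1 outcome vector of length n.
#' @param seed Integer seed for stochastic fitters.
#' @return An object of class `fitted_machine`.
#' @seealso [machine_predict()]
#' @export
fit_machine <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "machine_spec"))
  x <- as_feature_matrix(x)
  y <- check_binary(y, "y")
  if (nrow(x) != length(y)) stop("x and y sizes disagree", call. = FALSE)
  fit <- if (length(unique(y)) < 2L) {
    list(kind = "constant", value = y[1L])
  } else {
    with_seed(seed, fit_machine_impl(spec, x, y))
  }
  structure(list(spec = spec, fit = fit, p = ncol(x), seed = as.integer(seed)),
            class = "fitted_machine")
}

fit_machine_impl <- function(spec, x, y) {
  hp <- spec$hyperparams
  yf <- factor(y, levels = c(0L, 1L))
  switch(spec$family,
    random_forest = {
      nodesize <- max(1L, ceiling(hp$min_leaf_fraction * nrow(x)))
      list(kind = "rf",
           model = randomForest::randomForest(x, yf, ntree = hp$n_trees,
                                              nodesize = nodesize))
    },
    knn = {
      # lazy learner: keep the training set; k cannot exceed it
      list(kind = "knn", x = x, y = y,
           k = min(as.integer(hp$k), nrow(x)))
    },
    svm = {
      list(kind = "svm",
           model = e1071::svm(x, yf, kernel = hp$kernel, degree = hp$degree,
                              probability = TRUE))
    }
  )
}

#' @export
print.fitted_machine <- function(x, ...) {
  cat("<fitted_machine> ")
  print(x$spec)
  invisible(x)
}

#' Predict with a fitted base machine
#'
#' In `"probability"` mode returns the machine's class-1 probability,
#' clipped into \[0,1\]; in `"pure_class"` mode returns hard 0/1 labels
#' (as numeric 0/1 values, which double as degenerate probabilities).
#'
#' @param machine A [fit_machine()] result.
#' @param newdata Feature matrix with the fit-time column count.
#' @return Numeric vector in \[0,1\], one value per row of `newdata`.
#' @export
machine_predict <- function(machine, newdata) {
  stopifnot(inherits(machine, "fitted_machine"))
  newdata <- as_feature_matrix(newdata)
  if (ncol(newdata) != machine$p) {
    stop("newdata has ", ncol(newdata), " columns; machine was fitted on ",
         machine$p, call. = FALSE)
  }
  fit <- machine$fit
  prob_mode <- machine$spec$mode == "probability"
  p1 <- switch(fit$kind,
    constant = rep(as.numeric(fit$value), nrow(newdata)),
    rf = {
      if (prob_mode) {
        unname(stats::predict(fit$model, newdata, type = "prob")[, "1"])
      } else {
        as.numeric(as.character(stats::predict(fit$model, newdata, type = "response")))
      }
    },
    knn = {
      # tie votes are broken by RNG inside class::knn; seed them so that
      # predictions are deterministic given the fitted machine
      pred <- with_seed(machine$seed,
        class::knn(fit$x, newdata, factor(fit$y, levels = c(0L, 1L)),
                   k = fit$k, prob = TRUE, use.all = TRUE))
      win <- attr(pred, "prob") # vote share of the winning class
      lab <- as.numeric(as.character(pred))
      if (prob_mode) ifelse(lab == 1, win, 1 - win) else lab
    },
    svm = {
      if (prob_mode) {
        pred <- stats::predict(fit$model, newdata, probability = TRUE)
        unname(attr(pred, "probabilities")[, "1"])
      } else {
        as.numeric(as.character(stats::predict(fit$model, newdata)))
      }
    }
  )
  clip_probability(p1)
}
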