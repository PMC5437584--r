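#' Two-machine toy configuration for the worked cell-table example
#'
#' A fixed two-machine configuration whose cell (0,1) holds the known
#' outcomes 0,0,0,1 — so a test point routed there gets probability 3/4
#' for class 0 and 1/4 for class 1, and is declared class 0 at the 50%
#' cut-point. The other three cells are populated with arbitrary pure
#' contents ((0,0): two 0s; (1,0): one 1; (1,1): two 1s) so the Hamming
#' fallback geometry can be exercised: with cell (0,1) deleted, a (0,1)
#' query pools cells (0,0) and (1,1), both at distance 1.
#'
#' @return List with `train_predictions` (9 x 2 binary matrix),
#'   `train_outcomes` (length-9 binary vector) and `test_vector` `c(0, 1)`.
#' @examples
#' fx <- two_machine_fixture()
#' tab <- build_cell_table(fx$train_predictions, fx$train_outcomes)
#' estimate_probability(fx$test_vector, tab)$prob_class1 # 0.25
#' @export
two_machine_fixture <- function() {
  preds <- rbind(
    matrix(c(0L, 1L), 4L, 2L, byrow = TRUE),  # cell (0,1): outcomes 0,0,0,1
    matrix(c(0L, 0L), 2L, 2L, byrow = TRUE),  # cell (0,0): outcomes 0,0
    matrix(c(1L, 0L), 1L, 2L, byrow = TRUE),  # cell (1,0): outcome 1
    matrix(c(1L, 1L), 2L, 2L, byrow = TRUE)   # cell (1,1): outcomes 1,1
  )
  outcomes <- c(0L, 0L, 0L, 1L, 0L, 0L, 1L, 1L, 1L)
  list(train_predictions = preds, train_outcomes = outcomes,
       test_vector = c(0L, 1L))
}

#' Simulate a two-class Gaussian mixture with known Bayes error
#'
#' Equal class priors; class 0 is N(0, I_d), class 1 is N(delta * e1, I_d)
#' (mean shifted by `delta` along the first axis, unit spherical
#' covariance). Under this design the optimal rule thresholds the first
#' coordinate at `delta / 2` and the Bayes error is `pnorm(-delta / 2)` —
#' see [bayes_error()] — giving a benchmark with a known optimum for
#' testing that the crowd tracks its best member.
#'
#' @param n_per_class Samples per class.
#' @param delta Non-negative class-mean separation; default 2.
#' @param d Feature dimension; default 2 (kept low so that consistent
#'   members approach the Bayes rate at moderate n).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A [crowd_dataset()] with `2 * n_per_class` rows (class 0 block
#'   first).
#' @export
gaussian_mixture <- function(n_per_class, delta = 2, d = 2L, seed = 1L) {
  stopifnot(n_per_class >= 1L, delta >= 0, d >= 1L)
  n <- 2L * n_per_class
  X <- with_seed(seed, matrix(stats::rnorm(n * d), n, d))
  X[(n_per_class + 1L):n, 1L] <- X[(n_per_class + 1L):n, 1L] + delta
  colnames(X) <- paste0("x", seq_len(d))
  crowd_dataset(X, rep(c(0L, 1L), each = n_per_class))
}

#' Bayes error of the Gaussian-mixture benchmark
#'
#' For equal priors, unit spherical covariance and mean separation `delta`
#' along one axis, the minimal achievable misclassification probability is
#' `pnorm(-delta / 2)`.
#'
#' @param delta Non-negative class-mean separation.
#' @return Probability in (0, 0.5].
#' @examples
#' bayes_error(0) # 0.5
#' bayes_error(2) # pnorm(-1), about 0.1587
#' @export
bayes_error <- function(delta) {
  if (any(delta < 0)) stop("delta must be non-negative", call. = FALSE)
  stats::pnorm(-delta / 2)
}

#' Crowd-versus-best-member optimality experiment
#'
#' Repeatedly simulates the Gaussian-mixture benchmark, fits the crowd and
#' its base machines on a training set, and measures held-out percent
#' error for the crowd and for every member. The quantity of interest is
#' whether the crowd's mean error stays within Monte-Carlo noise of the
#' best single member's — the finite-sample face of the crowd's guarantee
#' of being at least as good as the best machine in the family given
#' sufficient data — and how close both come to the known Bayes error.
#'
#' @param delta Class separation; default 2.
#' @param n_per_class Training samples per class; default 1000.
#' @param n_test_per_class Held-out samples per class; default 1000.
#' @param machines Registry; default [crowd_registry(3)].
#' @param n_seeds Number of independent replicates; default 20.
#' @param seed Base seed; replicate r uses seeds derived from `seed + r`.
#' @param d Feature dimension; default 2.
#' @return List with `crowd_errors` and `best_member_errors` (per
#'   replicate), their means, `mean_member_errors` (per machine), and
#'   `bayes` (the closed-form Bayes error).
#' @export
optimality_experiment <- function(delta = 2, n_per_class = 1000L,
                                  n_test_per_class = 1000L,
                                  machines = crowd_registry(3),
                                  n_seeds = 20L, seed = 1L, d = 2L) {
  machines <- validate_registry(machines)
  crowd_err <- best_err <- numeric(n_seeds)
  member_err <- matrix(NA_real_, n_seeds, length(machines),
                       dimnames = list(NULL, names(machines)))
  for (r in seq_len(n_seeds)) {
    s <- seed + 1000L * r
    train <- gaussian_mixture(n_per_class, delta = delta, d = d, seed = s)
    test <- gaussian_mixture(n_test_per_class, delta = delta, d = d, seed = s + 1L)
    model <- optimal_crowd(train$X, train$y, machines = machines, seed = s)
    for (i in seq_along(model$machines)) {
      lab <- binarize(machine_predict(model$machines[[i]], test$X))
      member_err[r, i] <- percent_error(lab, test$y)
    }
    crowd_err[r] <- percent_error(predict(model, test$X, type = "label"), test$y)
    best_err[r] <- min(member_err[r, ])
  }
  list(crowd_errors = crowd_err, best_member_errors = best_err,
       member_errors = member_err,
       mean_crowd_error = mean(crowd_err),
       mean_best_member_error = mean(best_err),
       mean_member_errors = colMeans(member_err),
       bayes = bayes_error(delta))
}
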