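# Internal helpers shared across the package.

# Run `code` under set.seed(seed) and restore the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Validate a 0/1 vector (no NAs), returning it as integer.
check_binary <- function(x, what = "values") {
  x <- as.integer(x)
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    stop(sprintf("%s must contain only 0 and 1", what), call. = FALSE)
  }
  x
}

as_feature_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  x
}
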