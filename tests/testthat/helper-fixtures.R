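# Shared fixtures, all generated in code.

# Small well-separated two-class dataset for fast machine fits.
small_gaussian <- function(n_per_class = 30, delta = 2.5, seed = 42) {
  gaussian_mixture(n_per_class, delta = delta, seed = seed)
}

# Random occupied-cell table over M machines (for oracle comparisons).
random_cell_table <- function(M, n = 40, seed = 1) {
  with_seed_local(seed, {
    preds <- matrix(sample(0:1, n * M, replace = TRUE), n, M)
    build_cell_table(preds, sample(0:1, n, replace = TRUE))
  })
}

# Seed scoping for test code without touching global options.
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Brute-force nearest-cell oracle: exhaustive scan with plain loops.
brute_force_nearest <- function(query, table) {
  d <- vapply(table$keys, function(k) {
    bits <- as.integer(strsplit(k, "")[[1]])
    sum(bits != query)
  }, integer(1))
  d_star <- min(d)
  list(d_star = d_star, keys = unname(table$keys[d == d_star]))
}

# Synthetic stand-in for the UCI breast-cancer file layout: 699 records,
# 9 integer features in 1..10, labels 2 (negative) / 4 (positive), 16
# records carrying a missing "?" (14 negative, 2 positive), so complete
# cases come to 683 = 444 + 239. The values are random; only the layout
# and the counts mirror the documented structure.
write_synthetic_bc_file <- function(path, seed = 7) {
  with_seed_local(seed, {
    n0 <- 458; n1 <- 241
    n <- n0 + n1
    X <- matrix(sample(1:10, n * 9, replace = TRUE), n, 9)
    y <- c(rep(2, n0), rep(4, n1))
    rows <- cbind(seq_len(n) + 1e6, X, y) # leading id column, UCI-style
    rows <- apply(rows, 2, as.character)
    miss <- c(sample(seq_len(n0), 14), n0 + sample(seq_len(n1), 2))
    for (i in miss) rows[i, 1 + sample(9, 1)] <- "?"
    perm <- sample(n)
    writeLines(apply(rows[perm, ], 1, paste, collapse = ","), path)
  })
  invisible(path)
}
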