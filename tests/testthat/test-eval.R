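test_that("read_uci_csv parses records, flags missing cells, maps labels", {
  path <- withr::local_tempfile(fileext = ".data")
  writeLines(c("1,2,0", "4,?,1", "7,8,1"), path)
  rec <- read_uci_csv(path)
  expect_identical(dim(rec$X), c(3L, 2L))
  expect_identical(rec$missing, c(FALSE, TRUE, FALSE))
  expect_identical(rec$y, c(0L, 1L, 1L))

  # unknown label value is an error when the label set is declared
  bad <- withr::local_tempfile(fileext = ".data")
  writeLines(c("1,2,2", "3,4,7"), bad)
  expect_error(read_uci_csv(bad, negative_label = 2, positive_label = 4),
               "unknown class label")
  # non-numeric feature cells are an error with a line number
  nn <- withr::local_tempfile(fileext = ".data")
  writeLines(c("1,2,0", "oops,3,1"), nn)
  expect_error(read_uci_csv(nn), "line.*2")
})

test_that("complete_case_filter keeps exactly the complete rows", {
  path <- withr::local_tempfile(fileext = ".data")
  writeLines(c("1,2,0", "4,?,1", "7,8,1"), path)
  rec <- read_uci_csv(path)
  ds <- suppressMessages(complete_case_filter(rec))
  expect_identical(nrow(ds$X), 2L)
  expect_identical(attr(ds, "n_removed"), 1L)

  # no missing values: identity
  clean <- withr::local_tempfile(fileext = ".data")
  writeLines(c("1,2,0", "7,8,1"), clean)
  ds2 <- suppressMessages(complete_case_filter(read_uci_csv(clean)))
  expect_identical(nrow(ds2$X), 2L)

  allmiss <- withr::local_tempfile(fileext = ".data")
  writeLines(c("?,2,0", "1,?,1"), allmiss)
  expect_error(suppressMessages(complete_case_filter(read_uci_csv(allmiss))),
               "no complete cases")
})

test_that("min_max_scale fits on training data only and handles edges", {
  X <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  sc <- min_max_scale(X)
  expect_equal(unname(sc$train[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(sc$train[, "b"]), c(0, 0, 0)) # constant feature
  # values outside the training range are preserved, not clipped
  out <- apply_scaler(sc$scaler, cbind(a = c(0, 8), b = c(5, 9)))
  expect_equal(unname(out[, "a"]), c(-0.5, 1.5))
  # leakage guard: scaling train+test together changes the map
  sc_global <- min_max_scale(rbind(X, c(8, 5)))
  expect_false(isTRUE(all.equal(sc$scaler$range, sc_global$scaler$range)))
})

test_that("balanced_subsample draws exact per-class counts deterministically", {
  d <- gaussian_mixture(300, delta = 1, seed = 2)
  sub <- balanced_subsample(d, 200, seed = 5)
  expect_identical(nrow(sub$X), 400L)
  expect_identical(as.vector(table(sub$y)), c(200L, 200L))
  sub2 <- balanced_subsample(d, 200, seed = 5)
  expect_identical(sub$X, sub2$X)
  expect_error(balanced_subsample(d, 301, seed = 1), "fewer than")
})

test_that("percent_error is the misclassification fraction", {
  expect_equal(percent_error(c(0, 1, 1, 0), c(0, 1, 0, 0)), 0.25)
  expect_equal(percent_error(c(1, 1), c(1, 1)), 0)
  expect_equal(percent_error(c(1, 0), c(0, 1)), 1)
  expect_error(percent_error(integer(), integer()), "empty")
  expect_error(percent_error(c(1), c(1, 0)), "lengths differ")
})

test_that("five_fold_cv partitions, stratifies and reproduces per seed", {
  d <- gaussian_mixture(30, delta = 2, seed = 3)
  cv <- five_fold_cv(d, crowd_registry(3), seed = 11)
  # each sample is held out exactly once
  expect_identical(sort(unique(cv$folds)), 1:5)
  expect_identical(length(cv$folds), 60L)
  # stratification: per-fold class counts within 1
  for (f in 1:5) {
    counts <- table(d$y[cv$folds == f])
    expect_lte(abs(diff(as.integer(counts))), 1L)
  }
  expect_true(all(cv$errors >= 0 & cv$errors <= 1))
  expect_true(all(cv$se >= 0))
  expect_identical(colnames(cv$errors), c(names(crowd_registry(3)), "crowd"))
  # determinism
  cv2 <- five_fold_cv(d, crowd_registry(3), seed = 11)
  expect_identical(cv$errors, cv2$errors)
  # standard orientation trains on ~4/5 of the data; inverted on ~1/5
  expect_identical(sum(cv$folds != 1), 48L)
  cv_inv <- five_fold_cv(d, crowd_registry(3), seed = 11, invert_folds = TRUE)
  expect_true(all(cv_inv$errors >= 0 & cv_inv$errors <= 1))
  # too few class members for 5 folds
  tiny <- crowd_dataset(matrix(rnorm(16), 8), c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_error(five_fold_cv(tiny, crowd_registry(3)), "at least")
})

test_that("five_fold_cv reports the synthetic crowd when asked", {
  d <- gaussian_mixture(25, delta = 2.5, seed = 4)
  cv <- five_fold_cv(d, crowd_registry(3), syn = TRUE, seed = 1)
  expect_true("crowd_syn" %in% colnames(cv$errors))
  expect_output(print(cv), "crowd_syn")
})

test_that("cell_histogram tabulates every occupied cell and conserves totals", {
  fx <- two_machine_fixture()
  tab <- build_cell_table(fx$train_predictions, fx$train_outcomes)
  h <- cell_histogram(tab)
  expect_s3_class(h, "cell_histogram")
  expect_identical(nrow(h), 4L)
  expect_identical(sum(h$total), 9L)
  expect_identical(h$n0 + h$n1, h$total)

  d <- small_gaussian(n_per_class = 30)
  fit <- optimal_crowd(d$X, d$y, machines = crowd_registry(3), seed = 1)
  expect_identical(sum(cell_histogram(fit)$total), 60L)
})

test_that("train-only scaling never sees the evaluation fold", {
  # put the range-defining extremes in the held-out part: a train-only
  # scaler must differ from one fitted on the union
  X <- matrix(c(1, 2, 3, 100), ncol = 1)
  train <- X[1:3, , drop = FALSE]
  sc_train <- min_max_scale(train)$scaler
  sc_union <- min_max_scale(X)$scaler
  expect_false(isTRUE(all.equal(sc_train$range, sc_union$range)))
  # and the transformed held-out value reflects only the training range
  expect_equal(unname(apply_scaler(sc_train, X[4, , drop = FALSE])[1, 1]),
               (100 - 1) / 2)
})
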