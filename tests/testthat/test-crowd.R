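test_that("fitted crowd partitions the training outcomes exactly", {
  d <- small_gaussian(n_per_class = 40)
  fit <- optimal_crowd(d$X, d$y, machines = crowd_registry(3), seed = 1)
  expect_s3_class(fit, "optimal_crowd")
  expect_identical(sum(lengths(fit$table$outcomes)), 80L)
  expect_identical(fit$table$M, 3L)
})

test_that("crowd predictions satisfy their invariants on random batches", {
  d <- small_gaussian(n_per_class = 40)
  fit <- optimal_crowd(d$X, d$y, machines = crowd_registry(3), seed = 1)
  probe <- gaussian_mixture(25, delta = 2.5, seed = 77)
  full <- predict(fit, probe$X, type = "full")
  expect_true(all(full$prob_class1 >= 0 & full$prob_class1 <= 1))
  expect_true(all(full$n_pooled >= 1))
  expect_true(all(full$d_star >= 0))
  expect_identical(full$label, as.integer(full$prob_class1 > 0.5))
  expect_identical(predict(fit, probe$X, type = "prob"), full$prob_class1)
  expect_error(predict(fit, probe$X[, 1, drop = FALSE]), "columns")
})

test_that("a degenerate crowd of identical machines recovers group means", {
  d <- small_gaussian(n_per_class = 30)
  # two kNN machines with identical k produce identical predictions
  reg <- list(machine_spec("a", "knn", k = 3), machine_spec("b", "knn", k = 3))
  fit <- optimal_crowd(d$X, d$y, machines = reg, seed = 1)
  expect_true(all(fit$table$keys %in% c("00", "11")))
  # crowd probability for a training point equals its group's outcome mean
  p3 <- machine_predict(fit$machines[[1]], d$X)
  grp <- binarize(p3)
  probs <- predict(fit, d$X, type = "prob")
  for (g in unique(grp)) {
    expect_equal(unique(probs[grp == g]), mean(d$y[grp == g]))
  }
})

test_that("permuting the machine order leaves predictions unchanged", {
  d <- small_gaussian(n_per_class = 30)
  reg <- list(machine_spec("k1", "knn", k = 1), machine_spec("k3", "knn", k = 3),
              machine_spec("k5", "knn", k = 5))
  probe <- gaussian_mixture(20, delta = 2.5, seed = 5)$X
  fit_fwd <- optimal_crowd(d$X, d$y, machines = reg, seed = 1)
  fit_rev <- optimal_crowd(d$X, d$y, machines = rev(reg), seed = 1)
  expect_identical(predict(fit_fwd, probe, type = "full"),
                   predict(fit_rev, probe, type = "full"))
})

test_that("non-0/1 outcome labels are encoded and decoded faithfully", {
  d <- small_gaussian(n_per_class = 25)
  y_lab <- ifelse(d$y == 1, "malignant", "benign")
  fit <- optimal_crowd(d$X, y_lab, machines = crowd_registry(3), seed = 1)
  lab <- predict(fit, d$X, type = "label")
  expect_true(all(lab %in% c("benign", "malignant")))
  # same fit on the 0/1 encoding gives the same decisions
  fit01 <- optimal_crowd(d$X, d$y, machines = crowd_registry(3), seed = 1)
  expect_identical(lab == "malignant", predict(fit01, d$X, type = "label") == 1L)
})

test_that("the formula interface matches the matrix interface", {
  d <- small_gaussian(n_per_class = 25)
  df <- data.frame(d$X, y = d$y)
  fit_f <- optimal_crowd(y ~ x1 + x2, data = df, machines = crowd_registry(3),
                         seed = 1)
  fit_m <- optimal_crowd(d$X, d$y, machines = crowd_registry(3), seed = 1)
  expect_identical(predict(fit_f, d$X, type = "prob"),
                   predict(fit_m, d$X, type = "prob"))
})

test_that("out-of-fold table construction is available and still partitions", {
  d <- small_gaussian(n_per_class = 30)
  fit <- optimal_crowd(d$X, d$y, machines = crowd_registry(3), seed = 1,
                       table_predictions = "out_of_fold")
  expect_identical(sum(lengths(fit$table$outcomes)), 60L)
  p <- predict(fit, d$X, type = "prob")
  expect_true(all(p >= 0 & p <= 1))
})

test_that("models survive an archive round trip", {
  d <- small_gaussian(n_per_class = 20)
  fit <- optimal_crowd(d$X, d$y, machines = crowd_registry(3), seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  crowd_save(fit, path)
  back <- crowd_load(path)
  probe <- gaussian_mixture(10, seed = 6)$X
  expect_identical(predict(fit, probe, type = "full"),
                   predict(back, probe, type = "full"))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(crowd_load(bad), "optimal_crowd")
})

test_that("print and summary report the model structure", {
  d <- small_gaussian(n_per_class = 20)
  fit <- optimal_crowd(d$X, d$y, machines = crowd_registry(3), seed = 1)
  expect_output(print(fit), "Optimal crowd classifier")
  expect_output(print(summary(fit)), "Largest cells")
})

test_that("a failing machine is reported by name", {
  d <- small_gaussian(n_per_class = 10)
  broken <- machine_spec("broken_svm", "svm")
  broken$hyperparams$kernel <- "no_such_kernel"
  expect_error(optimal_crowd(d$X, d$y, machines = list(broken), seed = 1),
               "broken_svm")
})
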