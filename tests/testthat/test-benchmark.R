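# Feature selection, classifier suite, sweeps, and rank-sum comparisons.

test_that("top-feature selection is deterministic with index tie-breaking", {
  imp <- rep(1, 499500)
  top <- select_top_features(imp, fraction = 0.01)
  expect_length(top, 4995)
  expect_equal(top, 1:4995)  # all-equal importances: first by position

  imp2 <- c(0.1, 0.9, 0.9, 0.5)
  expect_equal(select_top_features(imp2, n = 3), c(2, 3, 4))
  expect_error(select_top_features(imp2, n = 10), "available")

  df <- data.frame(feature = letters[1:6],
                   block = rep(c("conn", "grad"), each = 3),
                   importance = c(3, 1, 2, 9, 9, 9))
  expect_equal(select_top_features(df, n = 2, scope = "conn"), c(1, 3))
  expect_equal(select_top_features(df, n = 2, scope = "grad"), c(4, 5))
  expect_equal(select_top_features(df, n = 2), c(4, 5))
})

test_that("the majority dummy scores the majority rate with zero minority F1", {
  set.seed(2)
  n <- 135
  x <- matrix(rnorm(n * 6), n)
  y <- factor(rep(c("NC", "SCZ"), c(100, 35)), levels = c("NC", "SCZ"))
  covs <- cbind(age = rnorm(n), sex_M = rbinom(n, 1, 0.5), mean_fd = runif(n))
  sp <- split_cohort(y, 0.25, seed = 5)
  res <- run_classifier_suite(x, y, covs, sp$train, sp$holdout,
                              folds = 10, seed = 3)
  expect_equal(res$baselines$majority$accuracy, 25 / 34)
  expect_identical(res$baselines$majority$f1, 0)
  expect_true(all(res$cv$accuracy >= 0 & res$cv$accuracy <= 1))
  expect_true(all(res$cv$f1 >= 0 & res$cv$f1 <= 1))
  expect_equal(nrow(res$cv), 13 * 10)
})

test_that("a separable toy is solved perfectly and the argmax contract holds", {
  set.seed(6)
  n <- 100
  x <- rbind(matrix(rnorm(50 * 4, 0), 50), matrix(rnorm(50 * 4, 5), 50))
  y <- factor(rep(c("NC", "SCZ"), each = 50), levels = c("NC", "SCZ"))
  covs <- cbind(age = rnorm(n), mean_fd = runif(n))
  rows <- sample(n)
  res <- run_classifier_suite(x, y, covs, rows[1:80], rows[81:100],
                              folds = 10, seed = 4)
  lr <- res$summary[res$summary$classifier == "lr", ]
  expect_equal(lr$mean_cv_accuracy, 1)
  expect_equal(lr$mean_cv_f1, 1)

  # argmax contract with a rigged two-classifier suite
  always_right <- list(fit = function(x, y) list(y = y),
                       predict = function(m, x) {
                         factor(rep(c("NC", "SCZ"), length.out = nrow(x)),
                                levels = c("NC", "SCZ"))
                       })
  rigged <- list(
    good = list(fit = function(x, y) list(mu = colMeans(x[y == "SCZ", 1:4,
                                                          drop = FALSE])),
                predict = function(m, x) {
                  d <- sqrt(rowSums(sweep(x[, 1:4, drop = FALSE], 2, m$mu)^2))
                  factor(ifelse(d < 3, "SCZ", "NC"), levels = c("NC", "SCZ"))
                }),
    bad = always_right)
  res2 <- run_classifier_suite(x, y, covs, rows[1:80], rows[81:100],
                               classifiers = rigged, folds = 5, seed = 4)
  expect_equal(res2$best_classifier, "good")
})

test_that("best-classifier densities are a probability distribution", {
  set.seed(8)
  n <- 90
  x <- cbind(ifelse(rep(c(0, 1), c(60, 30)) == 1, 2, -2) + rnorm(n),
             matrix(rnorm(n * 9), n))
  colnames(x) <- sprintf("f%d", 1:10)
  y <- factor(rep(c("NC", "SCZ"), c(60, 30)), levels = c("NC", "SCZ"))
  covs <- cbind(age = rnorm(n), mean_fd = runif(n))
  fi <- data.frame(feature = colnames(x),
                   block = c(rep("conn", 5), rep("grad", 5)),
                   importance = c(10, 4:1, 5:1))
  fb <- structure(list(values = x,
                       block = factor(c(rep("conn", 5), rep("grad", 5)),
                                      levels = c("conn", "grad", "disp_nbr",
                                                 "disp_cntr")),
                       covariates = covs,
                       group = y, subject_id = sprintf("s%d", 1:n)),
                  class = "feature_blocks")
  sp <- split_cohort(y, 0.25, seed = 1)
  one <- list(lr = classifier_suite(1)$lr)
  sw <- sweep_feature_counts(fi, fb, counts = c(2, 4), types = c("conn", "grad"),
                             train_rows = sp$train, holdout_rows = sp$holdout,
                             folds = 5, seed = 2, classifiers = one)
  expect_equal(unname(sw$density["lr"]), 1)
  expect_equal(sum(sw$density), 1)
  expect_equal(nrow(sw$runs), 4)
  expect_error(sweep_feature_counts(fi, fb, counts = c(4, 2),
                                    types = "conn", train_rows = sp$train,
                                    holdout_rows = sp$holdout), "sorted")
  expect_error(sweep_feature_counts(fi, fb, counts = c(2, 99), types = "conn",
                                    train_rows = sp$train,
                                    holdout_rows = sp$holdout,
                                    folds = 5, seed = 2, classifiers = one),
               "exceeds available")
})

test_that("rank-sum comparisons match exact enumeration", {
  # identical vectors: U = n1 n2 / 2, not significant
  v <- c(1:13) / 10
  ct0 <- compare_feature_types(list(conn = v, grad = v))
  expect_equal(ct0$U, 13 * 13 / 2)
  expect_false(ct0$significant)

  # complete separation of two length-13 samples: U = 169,
  # exact two-sided p = 2 / choose(26, 13)
  ct <- compare_feature_types(list(conn = 101:113 / 100, grad = 1:13 / 100))
  expect_equal(ct$U, 169)
  expect_equal(ct$p, 2 / choose(26, 13), tolerance = 1e-12)
  expect_true(ct$significant)

  # decision rule at the corrected threshold
  expect_true(0.004 <= attr(ct, "alpha"))
  ct2 <- compare_feature_types(list(conn = c(5, 6, 7, 8), grad = c(1, 2, 3, 9)),
                               alpha = 0.01)
  expect_false(ct2$significant)

  expect_error(compare_feature_types(list(conn = 1:2, grad = 3:4)), "length >= 3")
  expect_error(compare_feature_types(list(a = 1:5, b = 1:5)), "reference")
})

test_that("label shuffling keeps every classifier inside the chance band", {
  set.seed(10)
  n <- 120
  x <- matrix(rnorm(n * 8), n)
  y <- factor(rep(c("NC", "SCZ"), c(80, 40)), levels = c("NC", "SCZ"))
  covs <- cbind(age = rnorm(n), mean_fd = runif(n))
  sp <- split_cohort(y, 0.25, seed = 2)
  res <- run_classifier_suite(x, y, covs, sp$train, sp$holdout,
                              folds = 5, seed = 3, keep_predictions = TRUE)
  # band level adjusted for 13 simultaneous checks (1 - 0.05 / 13)
  for (cl in names(res$cv_predictions)) {
    band <- chance_band(res$cv_predictions[[cl]], res$cv_truth,
                        B = 4000, level = 1 - 0.05 / 13, seed = 11)
    expect_gte(band$observed, band$lower)
    expect_lte(band$observed, band$upper)
  }
})
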