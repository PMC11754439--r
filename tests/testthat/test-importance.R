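# Feature assembly, blockwise PCA, split, permutation component importance,
# and inverse projection.

toy_features <- function(n = 8, seed = 2) {
  set.seed(seed)
  cohort <- data.frame(subject_id = sprintf("s%02d", 1:n),
                       group = factor(rep(c("NC", "SCZ"), length.out = n),
                                      levels = c("NC", "SCZ")),
                       age = rnorm(n, 35), sex = factor(rep(c("F", "M"),
                                                            length.out = n)),
                       site = factor(rep(c("x", "y"), each = n / 2)),
                       mean_fd = runif(n, 0.05, 0.3))
  assemble_features(matrix(rnorm(n * 3), n), matrix(rnorm(n * 2), n),
                    matrix(rnorm(n * 4), n), matrix(rnorm(n * 2), n), cohort)
}

test_that("assembly concatenates blocks in order with a correct block map", {
  fb <- toy_features()
  expect_equal(ncol(fb$values), 11)
  expect_equal(as.character(fb$block),
               rep(c("conn", "grad", "disp_nbr", "disp_cntr"), c(3, 2, 4, 2)))
  expect_true(all(c("age", "sex_M", "site_x", "site_y", "mean_fd") %in%
                  colnames(fb$covariates)))
  expect_error(assemble_features(matrix(0, 3, 2), matrix(0, 4, 2),
                                 matrix(0, 4, 2), matrix(0, 4, 2),
                                 data.frame(subject_id = 1:4,
                                            group = c("NC", "NC", "SCZ", "SCZ"),
                                            age = 1, sex = "F", site = "x",
                                            mean_fd = 0.1)),
               "subject mismatch")
})

test_that("permuting subject order permutes rows only", {
  set.seed(4)
  n <- 8
  cohort <- data.frame(subject_id = sprintf("s%02d", 1:n),
                       group = rep(c("NC", "SCZ"), 4), age = rnorm(n),
                       sex = "F", site = "x", mean_fd = runif(n))
  b <- replicate(4, matrix(rnorm(n * 3), n), simplify = FALSE)
  fb <- assemble_features(b[[1]], b[[2]], b[[3]], b[[4]], cohort)
  perm <- sample(n)
  fbp <- assemble_features(b[[1]][perm, ], b[[2]][perm, ], b[[3]][perm, ],
                           b[[4]][perm, ], cohort[perm, ])
  expect_equal(unname(fbp$values), unname(fb$values[perm, ]))
  expect_identical(fbp$block, fb$block)
})

test_that("the stratified split preserves the class ratio and partitions", {
  y <- factor(rep(c("NC", "SCZ"), c(100, 35)), levels = c("NC", "SCZ"))
  sp <- split_cohort(y, 0.25, seed = 9)
  expect_length(sp$holdout, 34)  # 25 NC + 9 SCZ
  expect_equal(sum(y[sp$holdout] == "SCZ"), 9)
  expect_equal(sort(c(sp$train, sp$holdout)), 1:135)
  expect_length(intersect(sp$train, sp$holdout), 0)
  expect_identical(sp, split_cohort(y, 0.25, seed = 9))
  expect_false(identical(sp$holdout, split_cohort(y, 0.25, seed = 10)$holdout))
  expect_error(split_cohort(factor(rep("NC", 5))), "two classes")
})

test_that("block PCA hits the variance target with the two-component floor", {
  set.seed(31)
  n <- 300
  cohort <- data.frame(subject_id = sprintf("s%03d", 1:n),
                       group = rep(c("NC", "SCZ"), length.out = n),
                       age = rnorm(n), sex = "F", site = "x",
                       mean_fd = runif(n))
  iid <- matrix(rnorm(n * 100), n)            # flat spectrum
  spike <- cbind(rnorm(n, sd = 30), matrix(rnorm(n * 9, sd = 0.3), n))
  fb <- assemble_features(iid, spike, matrix(rnorm(n * 5), n),
                          matrix(rnorm(n * 28), n), cohort)
  pca <- fit_block_pca(fb, variance_target = 0.20, train_rows = 1:n)
  # independent oracle: component count from a dense eigendecomposition of
  # the train covariance (smallest n >= 2 with cumulative variance >= 20%)
  ev <- eigen(stats::cov(iid), symmetric = TRUE, only.values = TRUE)$values
  oracle_n <- max(2, which(cumsum(ev) / sum(ev) >= 0.20)[1])
  expect_equal(pca$blocks$conn$n_components, oracle_n)
  # flat population spectrum: ~20 components at 20%, fewer in finite samples
  # (Wishart eigenvalue spread inflates the leading sample eigenvalues)
  expect_gte(pca$blocks$conn$n_components, 8)
  expect_lte(pca$blocks$conn$n_components, 25)
  expect_gte(sum(pca$blocks$conn$variance_ratio), 0.20)
  # 99%-spike block floors at 2 components
  expect_equal(pca$blocks$grad$n_components, 2)
  # exempt block keeps everything
  expect_equal(pca$blocks$disp_cntr$n_components, 28)
  # orthonormal axes
  w <- pca$blocks$conn$rotation
  expect_equal(crossprod(w), diag(ncol(w)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # a one-feature block is kept whole, with a warning
  expect_warning(
    fit_block_pca(
      assemble_features(iid[, 1:3], spike[, 1:2], matrix(rnorm(n * 2), n),
                        matrix(rnorm(n), n, 1), cohort),
      0.2, train_rows = 1:n),
    "< 2 features")
})

test_that("PCA and scalers never touch holdout rows", {
  fb <- toy_features(n = 28, seed = 6)
  tr <- 1:20
  pca1 <- fit_block_pca(fb, 0.5, train_rows = tr)
  m1 <- fit_importance_model(transform_blocks(pca1, fb), fb$covariates,
                             fb$group, tr)
  # corrupt the holdout rows wildly and refit on the same train rows
  fb2 <- fb
  fb2$values[21:28, ] <- fb2$values[21:28, ] * 100 + 7
  pca2 <- fit_block_pca(fb2, 0.5, train_rows = tr)
  expect_equal(pca1$blocks, pca2$blocks)
  expect_equal(transform_blocks(pca1, fb, rows = tr),
               transform_blocks(pca2, fb2, rows = tr))
  m2 <- fit_importance_model(transform_blocks(pca2, fb2), fb2$covariates,
                             fb2$group, tr)
  expect_equal(m1$beta, m2$beta)
  expect_equal(m1$scaler, m2$scaler)
})

test_that("a zero-coefficient component has exactly zero importance", {
  fb <- toy_features(n = 40, seed = 8)
  sp <- list(train = 1:30, holdout = 31:40)
  pca <- fit_block_pca(fb, 0.5, train_rows = sp$train)
  comps <- transform_blocks(pca, fb)
  model <- fit_importance_model(comps, fb$covariates, fb$group, sp$train)
  model$beta[2] <- 0
  rep_ <- permutation_component_importance(model, comps, fb$covariates,
                                           fb$group, sp$holdout,
                                           n_perm = 50, seed = 3)
  expect_identical(rep_$component_importance$mean[2], 0)
  expect_identical(rep_$component_importance$sd[2], 0)
  expect_error(permutation_component_importance(model, comps, fb$covariates,
                                                fb$group, sp$holdout,
                                                n_perm = 0), "n_perm")
})

test_that("a single perfectly predictive component loses half its accuracy", {
  set.seed(12)
  n <- 200
  y <- factor(rep(c("NC", "SCZ"), each = n / 2), levels = c("NC", "SCZ"))
  comps <- cbind(comp = ifelse(y == "SCZ", 1, -1) + rnorm(n, sd = 0.01))
  attr(comps, "block") <- "conn"
  covs <- cbind(age = rnorm(n), mean_fd = runif(n))
  tr <- c(1:75, 101:175); ho <- setdiff(1:n, tr)
  model <- fit_importance_model(comps, covs, y, tr)
  rep_ <- permutation_component_importance(model, comps, covs, y, ho,
                                           n_perm = 2000, seed = 5)
  expect_equal(rep_$baseline_accuracy, 1)
  # balanced holdout: permuted accuracy concentrates near 0.5
  expect_equal(rep_$component_importance$mean[1], 0.5, tolerance = 0.03)
})

test_that("importance reports are reproducible under a fixed seed", {
  fb <- toy_features(n = 24, seed = 10)
  sp <- split_cohort(fb, 0.25, seed = 2)
  pca <- fit_block_pca(fb, 0.5, train_rows = sp$train)
  comps <- transform_blocks(pca, fb)
  model <- fit_importance_model(comps, fb$covariates, fb$group, sp$train)
  r1 <- permutation_component_importance(model, comps, fb$covariates,
                                         fb$group, sp$holdout, 100, seed = 6)
  r2 <- permutation_component_importance(model, comps, fb$covariates,
                                         fb$group, sp$holdout, 100, seed = 6)
  expect_identical(r1, r2)
})

test_that("inverse projection obeys identity and one-hot contracts", {
  # hand-built model: identity projection returns |importance|
  rot <- diag(3)
  rownames(rot) <- paste0("f", 1:3)
  pca <- structure(list(blocks = list(conn = list(rotation = rot,
                                                  n_components = 3,
                                                  cols = 1:3))),
                   class = "pca_block_model")
  rep_ <- structure(list(component_importance = data.frame(
    component = paste0("conn_pc", 1:3), block = "conn",
    mean = c(0.2, -0.1, 0), sd = 0)), class = "importance_report")
  fi <- importance_to_feature_space(rep_, pca)
  expect_equal(fi$importance, c(0.2, 0.1, 0))
  fi_s <- importance_to_feature_space(rep_, pca, signed = TRUE)
  expect_equal(fi_s$importance, c(0.2, -0.1, 0))

  # one-hot loading: importance lands on the loaded feature only
  rot1 <- matrix(c(0, 0, 1), 3, 1, dimnames = list(paste0("f", 1:3), NULL))
  pca1 <- structure(list(blocks = list(conn = list(rotation = rot1,
                                                   n_components = 1,
                                                   cols = 1:3))),
                    class = "pca_block_model")
  rep1 <- structure(list(component_importance = data.frame(
    component = "conn_pc1", block = "conn", mean = 0.4, sd = 0)),
    class = "importance_report")
  fi1 <- importance_to_feature_space(rep1, pca1)
  expect_equal(fi1$importance, c(0, 0, 0.4))

  bad <- rep_
  bad$component_importance <- bad$component_importance[1:2, ]
  expect_error(importance_to_feature_space(bad, pca), "importances vs")
})

# The Spearman comparison of back-projected importance against the
# brute-force per-feature permutation oracle runs with the end-to-end checks
# in test-acceptance.R (it needs a large evaluation sample to resolve ranks).
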