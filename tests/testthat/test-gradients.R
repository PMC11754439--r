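# Fisher z, thresholding, PCA gradients, Procrustes, edge vectorization.

test_that("fisher z transform matches the closed form and preserves symmetry", {
  m <- random_corr(8, seed = 4)
  z <- fisher_z(m)
  expect_equal(z, t(z))
  expect_equal(unname(diag(z)), rep(0, 8))
  expect_equal(z[1, 2], atanh(m[1, 2]))
  m2 <- diag(3); m2[1, 2] <- m2[2, 1] <- 0.5
  expect_equal(fisher_z(m2)[1, 2], 0.5493061, tolerance = 1e-6)
  expect_equal(fisher_z(m2)[1, 3], 0)
  m3 <- diag(3); m3[1, 2] <- m3[2, 1] <- 1
  expect_warning(z3 <- fisher_z(m3), "clipped")
  expect_true(is.finite(z3[1, 2]))
})

test_that("row-wise thresholding keeps the top density fraction per row", {
  set.seed(11)
  row <- sample(seq(-5, 4.5, by = 1))  # 10 distinct values
  m <- rbind(row, row, deparse.level = 0)
  m <- rbind(m, matrix(rnorm(80), 8, 10))
  th <- threshold_matrix(m, density = 0.10)
  expect_equal(sum(th[1, ] != 0), 1)
  expect_equal(th[1, which.max(m[1, ])], max(m[1, ]))

  # brute-force oracle on a half-negative row: no negative survivors at 10%
  neg_row <- c(sort(rnorm(5, -3)), sort(abs(rnorm(5, 2))))
  mn <- matrix(rep(neg_row, 10), 10, byrow = TRUE)
  thn <- threshold_matrix(mn, density = 0.10)
  survivors <- thn[1, thn[1, ] != 0]
  oracle <- sort(neg_row, decreasing = TRUE)[1]
  expect_equal(unname(survivors), oracle)
  expect_true(all(survivors > 0))

  # idempotent on survivors (all-positive retained values)
  z <- abs(random_corr(20, seed = 5)) + 0.01; diag(z) <- 0
  t1 <- threshold_matrix(z, 0.2)
  t2 <- threshold_matrix(t1, 0.2)
  expect_identical(t1 != 0, t2 != 0)
  expect_equal(t1, t2)
})

test_that("gradients match a dense eigendecomposition oracle on a 12-parcel toy", {
  m <- random_corr(12, t = 60, seed = 9)
  th <- threshold_matrix(fisher_z(m), 0.25)
  g <- compute_gradients(th, 5)
  # independent oracle: eigen of the covariance of centered columns
  xc <- scale(th, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  oracle_scores <- xc %*% ev$vectors[, 1:5]
  for (k in 1:5) {
    expect_equal(abs(g$scores[, k]), unname(abs(oracle_scores[, k])),
                 tolerance = 1e-8)
    expect_equal(g$variance_ratio[k], ev$values[k] / sum(ev$values),
                 tolerance = 1e-10)
  }
})

test_that("gradient scores are orthogonal with non-increasing variance ratios", {
  m <- random_corr(15, seed = 14)
  g <- compute_gradients(threshold_matrix(fisher_z(m), 0.2), 6)
  cp <- crossprod(g$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  expect_true(all(diff(g$variance_ratio) <= 1e-12))
  expect_lte(sum(g$variance_ratio), 1 + 1e-8)
  expect_error(compute_gradients(m, 16), "exceeds parcel count")
})

test_that("a rank-1 centered matrix loads all variance on the first gradient", {
  u <- seq(-1, 1, length.out = 10)
  m <- outer(u, rnorm(10))
  g <- compute_gradients(m, 2)
  expect_equal(g$variance_ratio[1], 1, tolerance = 1e-10)
})

test_that("the sign convention is deterministic", {
  m <- random_corr(15, seed = 20)
  th <- threshold_matrix(fisher_z(m), 0.2)
  g1 <- compute_gradients(th, 4)
  g2 <- compute_gradients(th, 4)
  expect_identical(g1$scores, g2$scores)
  for (k in 1:4) {
    expect_gt(g1$loadings[which.max(abs(g1$loadings[, k])), k], 0)
  }
})

test_that("Procrustes recovers a planted orthogonal rotation exactly", {
  m <- random_corr(20, seed = 6)
  ref <- compute_gradients(threshold_matrix(fisher_z(m), 0.2), 5)

  self <- procrustes_align(ref, ref)
  expect_equal(self$rotation, diag(5), tolerance = 1e-8)
  expect_equal(self$scores, ref$scores, tolerance = 1e-8)

  q <- random_orthogonal(5, seed = 13)
  rotated <- ref
  rotated$scores <- ref$scores %*% q
  back <- procrustes_align(rotated, ref)
  expect_lt(norm(back$scores - ref$scores, "F"), 1e-8)
  expect_equal(back$rotation, t(q), tolerance = 1e-8)

  # inter-parcel distances are preserved
  expect_equal(as.matrix(dist(back$scores)), as.matrix(dist(rotated$scores)),
               tolerance = 1e-8)

  bad <- ref; bad$scores <- bad$scores[, 1:3]
  expect_error(procrustes_align(bad, ref), "dimension mismatch")
})

test_that("alignment never increases the Frobenius distance to the reference", {
  ref <- compute_gradients(threshold_matrix(fisher_z(random_corr(18, seed = 2)),
                                            0.2), 4)
  for (s in 1:5) {
    g <- compute_gradients(threshold_matrix(fisher_z(random_corr(18, seed = 30 + s)),
                                            0.2), 4)
    before <- norm(g$scores - ref$scores, "F")
    after <- norm(procrustes_align(g, ref)$scores - ref$scores, "F")
    expect_lte(after, before + 1e-12)
  }
})

test_that("edge vectorization is row-major upper-triangle and invertible", {
  m <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3)
  v <- vectorize_edges(m)
  expect_equal(unname(v), c(.1, .2, .3))
  expect_equal(names(v), c("e1_2", "e1_3", "e2_3"))

  mc <- random_corr(9, seed = 8)
  expect_equal(devectorize_edges(vectorize_edges(mc)), mc,
               ignore_attr = TRUE)
  expect_equal(length(vectorize_edges(random_corr(40, seed = 1))),
               n_edges(40))

  asym <- diag(3); asym[1, 2] <- 0.5
  expect_error(vectorize_edges(asym), "asymmetric")
})

test_that("the reference cohort aligns to itself without distortion", {
  sim <- small_cohort()
  ref <- reference_gradients(sim$cohort, sim$matrices, 6)
  expect_false(ref$aligned)
  re <- procrustes_align(ref, ref)
  expect_equal(re$scores, ref$scores, tolerance = 1e-8)
})
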