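# Shared fixtures, built in code and cached per test session.

fixture_env <- new.env(parent = emptyenv())

# Small 7-network cohort with a planted effect; reused by several files.
small_cohort <- function() {
  if (is.null(fixture_env$small)) {
    labels <- make_network_labels(30, 7)
    edges <- plant_edges(labels, 10, seed = 21)
    eff <- effect_spec(target_edges = edges, delta = 0.3)
    fixture_env$small <- c(generate_cohort(80, 30, labels, eff, seed = 101),
                           list(edges = edges))
  }
  fixture_env$small
}

# Random orthogonal matrix via QR with fixed sign convention.
random_orthogonal <- function(d, seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(d * d), d))
  q <- qr.Q(qr_d)
  q %*% diag(sign(diag(qr.R(qr_d))), d)
}

# A valid correlation matrix from random time series.
random_corr <- function(p, t = 80, seed = 1) {
  set.seed(seed)
  stats::cor(matrix(rnorm(t * p), t, p))
}
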