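# Macroscale cortical gradients: Fisher z-transform, row-wise density
# thresholding, PCA embedding, Procrustes alignment to a reference, and edge
# vectorization.

#' Fisher z-transform a connectivity matrix
#'
#' The diagonal is set to 0 before the transform; off-diagonal correlations
#' with |r| = 1 are clipped to 1 - 1e-7 (with a warning) so the transform
#' stays finite.
#'
#' @param matrix Symmetric unit-diagonal correlation matrix.
#' @return Symmetric matrix of z values, zero diagonal.
#' @export
fisher_z <- function(matrix) {
  validate_connectivity(matrix)
  m <- matrix
  diag(m) <- 0
  if (any(abs(m) >= 1)) {
    warning("off-diagonal |r| = 1 clipped to 1 - 1e-7 before atanh")
    m[m >= 1] <- 1 - 1e-7
    m[m <= -1] <- -(1 - 1e-7)
  }
  z <- atanh(m)
  diag(z) <- 0
  z
}

#' Density-threshold a connectivity matrix
#'
#' Row-wise sparsification: per row, the top `ceiling(density * P)` values are
#' retained unchanged and everything else (including negative correlations)
#' is set to zero. Row-wise thresholding is the convention of the gradient
#' literature and yields a generally asymmetric sparse matrix;
#' `scope = "global"` instead keeps the overall top fraction of entries.
#'
#' @param z_matrix Square numeric matrix (typically Fisher z values).
#' @param density Fraction of values retained per row (default 0.10, i.e.
#'   discard the lowest 90 percent including negatives).
#' @param scope `"row"` (default) or `"global"`.
#' @return Matrix with the same dimensions, non-survivors zeroed.
#' @export
threshold_matrix <- function(z_matrix, density = 0.10, scope = c("row", "global")) {
  scope <- match.arg(scope)
  stopifnot(is.matrix(z_matrix), density > 0, density <= 1)
  p <- ncol(z_matrix)
  k <- ceiling(density * p)
  if (k < 1) stop("density ", density, " retains no values per row")
  out <- matrix(0, nrow(z_matrix), p, dimnames = dimnames(z_matrix))
  if (scope == "row") {
    for (r in seq_len(nrow(z_matrix))) {
      ord <- order(z_matrix[r, ], decreasing = TRUE)[seq_len(k)]
      out[r, ord] <- z_matrix[r, ord]
    }
  } else {
    ktot <- ceiling(density * length(z_matrix))
    ord <- order(z_matrix, decreasing = TRUE)[seq_len(ktot)]
    out[ord] <- z_matrix[ord]
  }
  out
}

#' Compute macroscale gradients by PCA
#'
#' Rows (parcels) are observations and columns (connectivity profiles) are
#' variables; columns are centered, not scaled. Scores are the projections
#' onto the leading principal axes. Eigenvector sign indeterminacy is removed
#' by a fixed convention: within each component, the loading of largest
#' absolute value is made positive.
#'
#' @param matrix Thresholded connectivity matrix (P x P).
#' @param n_components Number of gradients D (<= P).
#' @return An object of class `gradient_set`: list with `scores` (P x D),
#'   `variance_ratio` (length D, fractions of total variance), `loadings`
#'   (P x D principal axes), `aligned = FALSE`.
#' @export
compute_gradients <- function(matrix, n_components) {
  stopifnot(is.matrix(matrix))
  p <- nrow(matrix)
  if (n_components > p) {
    stop("n_components (", n_components, ") exceeds parcel count (", p, ")")
  }
  pc <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  d <- n_components
  scores <- pc$x[, seq_len(d), drop = FALSE]
  loadings <- pc$rotation[, seq_len(d), drop = FALSE]
  for (kk in seq_len(d)) {
    top <- which.max(abs(loadings[, kk]))
    if (loadings[top, kk] < 0) {
      loadings[, kk] <- -loadings[, kk]
      scores[, kk] <- -scores[, kk]
    }
  }
  colnames(scores) <- colnames(loadings) <- sprintf("G%d", seq_len(d))
  rownames(scores) <- rownames(matrix)
  structure(list(scores = scores,
                 variance_ratio = pc$sdev[seq_len(d)]^2 / total_var,
                 loadings = loadings,
                 aligned = FALSE),
            class = "gradient_set")
}

#' @method print gradient_set
#' @export
print.gradient_set <- function(x, ...) {
  cat("gradient_set:", nrow(x$scores), "parcels x", ncol(x$scores),
      "components;", if (x$aligned) "aligned" else "unaligned", "\n")
  cat("  leading variance ratios:",
      paste(sprintf("%.3f", utils::head(x$variance_ratio, 5)), collapse = " "),
      "\n")
  invisible(x)
}

#' Orthogonal Procrustes alignment of gradients to a reference
#'
#' Finds the orthogonal matrix Q (rotation + reflection, no scaling or
#' translation) minimizing the Frobenius distance between `subject$scores %*% Q`
#' and `reference$scores`. Inter-parcel distances are preserved exactly.
#'
#' @param subject,reference `gradient_set` objects with identical dimensions.
#' @return The subject `gradient_set` with aligned scores (`aligned = TRUE`)
#'   and the transform stored as `$rotation`.
#' @export
procrustes_align <- function(subject, reference) {
  s <- subject$scores; r <- reference$scores
  if (!all(dim(s) == dim(r))) {
    stop("dimension mismatch: subject ", paste(dim(s), collapse = "x"),
         " vs reference ", paste(dim(r), collapse = "x"))
  }
  sv <- svd(crossprod(s, r))
  q <- sv$u %*% t(sv$v)
  out <- subject
  out$scores <- s %*% q
  dimnames(out$scores) <- dimnames(s)
  out$rotation <- q
  out$aligned <- TRUE
  out
}

#' Gradients of a reference cohort's mean control matrix
#'
#' Builds the alignment reference the way a group-level template is built:
#' average the control-group connectivity matrices, Fisher z-transform,
#' threshold, and embed.
#'
#' @param cohort,matrices A cohort table and aligned matrix list.
#' @param n_components Number of gradients.
#' @param density Threshold density (default 0.10).
#' @param group Reference group label (default `"NC"`).
#' @return A `gradient_set`.
#' @export
reference_gradients <- function(cohort, matrices, n_components, density = 0.10,
                                group = "NC") {
  idx <- which(cohort$group == group)
  if (length(idx) == 0) stop("no subjects in reference group '", group, "'")
  mean_m <- Reduce(`+`, matrices[idx]) / length(idx)
  diag(mean_m) <- 1
  compute_gradients(threshold_matrix(fisher_z(mean_m), density), n_components)
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Row-major strict upper triangle (i < j): (1,2), (1,3), ..., (1,P), (2,3),
#' ... — the package-wide edge order (see [edge_index_table()]). A 1000-parcel
#' matrix yields 499,500 edge values.
#'
#' @param matrix Symmetric square matrix.
#' @param tol Symmetry tolerance.
#' @return Numeric vector of length `P(P-1)/2`, named `e<i>_<j>`.
#' @export
vectorize_edges <- function(matrix, tol = 1e-8) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (max(abs(matrix - t(matrix))) > tol) {
    stop("matrix is asymmetric beyond tolerance; edge vectorization undefined")
  }
  v <- t(matrix)[lower.tri(matrix)]
  et <- edge_index_table(nrow(matrix))
  names(v) <- sprintf("e%d_%d", et$i, et$j)
  v
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_edges()]; the diagonal is set to `diag_value`.
#'
#' @param edge_vector Length `P(P-1)/2` vector in package edge order.
#' @param diag_value Diagonal fill (default 1).
#' @return P x P symmetric matrix.
#' @export
devectorize_edges <- function(edge_vector, diag_value = 1) {
  n <- length(edge_vector)
  p <- (1 + sqrt(1 + 8 * n)) / 2
  if (abs(p - round(p)) > 1e-9) stop("length ", n, " is not P(P-1)/2 for integer P")
  p <- as.integer(round(p))
  m <- matrix(0, p, p)
  m[lower.tri(m)] <- edge_vector  # fills t(M) upper triangle row-major
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_value
  m
}
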