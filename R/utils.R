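# Shared helpers: edge indexing, matrix validation, stratified resampling.

#' Edge index table for the upper triangle of a square matrix
#'
#' Edges are enumerated in row-major order over the strict upper triangle
#' (`i < j`): (1,2), (1,3), ..., (1,P), (2,3), ... This ordering is the single
#' edge-indexing convention used throughout the package (vectorized
#' connectivity, importance tables, edge masks).
#'
#' @param n_parcels Number of parcels P.
#' @return A data.frame with columns `i`, `j` (1-based parcel indices) and
#'   one row per edge, `P(P-1)/2` rows in total.
#' @export
edge_index_table <- function(n_parcels) {
  stopifnot(n_parcels >= 2)
  i <- rep.int(seq_len(n_parcels - 1L), times = (n_parcels - 1L):1L)
  j <- unlist(lapply(seq_len(n_parcels - 1L), function(k) (k + 1L):n_parcels),
              use.names = FALSE)
  data.frame(i = i, j = j)
}

#' Number of upper-triangle edges for P parcels
#' @param n_parcels Number of parcels.
#' @return `P(P-1)/2`.
#' @export
n_edges <- function(n_parcels) {
  as.numeric(n_parcels) * (n_parcels - 1) / 2
}

# Validate a connectivity matrix: square, symmetric, unit diagonal,
# off-diagonal values in [-1, 1]. Returns the matrix invisibly.
validate_connectivity <- function(m, tol = 1e-8, what = "connectivity matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) != ncol(m)) {
    stop(what, " must be square, got ", nrow(m), "x", ncol(m), call. = FALSE)
  }
  if (anyNA(m)) stop(what, " contains missing values", call. = FALSE)
  if (max(abs(m - t(m))) > tol) {
    stop(what, " is not symmetric within tolerance ", tol, call. = FALSE)
  }
  if (max(abs(diag(m) - 1)) > tol) {
    stop(what, " must have unit diagonal", call. = FALSE)
  }
  off <- m[upper.tri(m)]
  if (any(abs(off) > 1 + tol)) {
    stop(what, " has off-diagonal values outside [-1, 1]", call. = FALSE)
  }
  invisible(m)
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin across folds so class ratios are preserved per fold.
make_stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  set.seed(as.integer(seed))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    if (length(idx) < k) {
      stop("class '", lev, "' has fewer members (", length(idx),
           ") than folds (", k, "); use fewer folds", call. = FALSE)
    }
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Binary F1 for a designated positive class; 0 when there are no true
# positives (covers the degenerate all-negative prediction).
f1_score <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

accuracy_score <- function(truth, pred) mean(as.character(truth) == as.character(pred))
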