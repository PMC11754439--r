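# Feature assembly: per-subject feature blocks (conn | grad | disp_nbr |
# disp_cntr), covariate encoding, blockwise PCA compression, and the
# stratified train/holdout split.

BLOCK_LEVELS <- c("conn", "grad", "disp_nbr", "disp_cntr")

#' Compute all four feature blocks for a cohort
#'
#' Per subject: the vectorized upper-triangle edges; the aligned gradient
#' embedding (PCA of the Fisher z-transformed, thresholded matrix, Procrustes
#' aligned to `reference`); the neighborhood-dispersion grid; and the 28-style
#' centroid dispersion values (3-gradient space, network medians).
#'
#' @param cohort,matrices Cohort table and aligned matrix list.
#' @param network_labels Parcel-to-network map.
#' @param reference Alignment reference (`gradient_set`), e.g. from
#'   [reference_gradients()] on a separate seeded reference cohort.
#' @param n_components Gradients per subject (default `P / 5`).
#' @param density Threshold density.
#' @param K_set,d_range Dispersion grid (defaults: [k_ladder()] restricted to
#'   K < P, and all computed gradients).
#' @return List of matrices `conn`, `grad`, `disp_nbr`, `disp_cntr` (subjects
#'   in rows) plus `gradient_sets` (per-subject aligned embeddings).
#' @export
compute_feature_blocks <- function(cohort, matrices, network_labels, reference,
                                   n_components = NULL, density = 0.10,
                                   K_set = NULL, d_range = NULL) {
  p <- length(network_labels)
  if (is.null(n_components)) n_components <- max(3, p %/% 5)
  if (is.null(K_set)) {
    K_set <- k_ladder()[k_ladder() < p]
    if (length(K_set) == 0) K_set <- max(1L, p %/% 10)
  }
  n <- nrow(cohort)
  grads <- vector("list", n)
  conn <- matrix(NA_real_, n, n_edges(p))
  for (s in seq_len(n)) {
    m <- matrices[[s]]
    conn[s, ] <- vectorize_edges(m)
    g <- compute_gradients(threshold_matrix(fisher_z(m), density), n_components)
    grads[[s]] <- procrustes_align(g, reference)
  }
  colnames(conn) <- names(vectorize_edges(matrices[[1]]))
  grad <- t(vapply(grads, function(g) as.numeric(g$scores),
                   numeric(p * n_components)))
  colnames(grad) <- sprintf("grad_p%d_g%d",
                            rep(seq_len(p), times = n_components),
                            rep(seq_len(n_components), each = p))
  nbr <- t(vapply(grads, function(g)
    neighborhood_dispersion_grid(g, K_set = K_set, d_range = d_range),
    numeric(length(nd_grid_features(p,
      if (is.null(d_range)) seq_len(n_components) else d_range, K_set)))))
  cntr <- t(vapply(grads, function(g)
    centroid_dispersion(g, network_labels)$values,
    numeric(length(unique(network_labels)) * (length(unique(network_labels)) + 1) / 2)))
  list(conn = conn, grad = grad, disp_nbr = nbr, disp_cntr = cntr,
       gradient_sets = grads)
}

#' Concatenate feature blocks into one subject-by-feature matrix
#'
#' Column order is conn | grad | disp_nbr | disp_cntr with a block label per
#' column; covariates (age, sex, site one-hot, mean FD) are attached
#' unencoded-by-blocks and are never part of the feature blocks. At full
#' scale (P = 1000, D = 200, five K values) the per-subject vector has
#' 499,500 + 200,000 + 1,000,000 + 28 = 1,699,528 entries.
#'
#' @param conn,grad,disp_nbr,disp_cntr Per-block subject-by-feature matrices.
#' @param cohort Cohort table aligned with block rows.
#' @return Object of class `feature_blocks`: `values` (n x F), `block`
#'   (factor per column), `covariates` (numeric design: age, sex_M, site
#'   one-hot, mean_fd), `group`, `subject_id`.
#' @export
assemble_features <- function(conn, grad, disp_nbr, disp_cntr, cohort) {
  blocks <- list(conn = as.matrix(conn), grad = as.matrix(grad),
                 disp_nbr = as.matrix(disp_nbr), disp_cntr = as.matrix(disp_cntr))
  ns <- vapply(blocks, nrow, integer(1))
  if (length(unique(ns)) != 1 || ns[1] != nrow(cohort)) {
    stop("subject mismatch across blocks/cohort: ",
         paste(c(ns, nrow(cohort)), collapse = ", "))
  }
  values <- do.call(cbind, blocks)
  colnames(values) <- unlist(lapply(names(blocks), function(b) {
    cn <- colnames(blocks[[b]])
    if (is.null(cn)) cn <- sprintf("%s_f%d", b, seq_len(ncol(blocks[[b]])))
    cn
  }), use.names = FALSE)
  block <- factor(rep(BLOCK_LEVELS, times = vapply(blocks, ncol, integer(1))),
                  levels = BLOCK_LEVELS)
  structure(list(values = values, block = block,
                 covariates = encode_covariates(cohort),
                 group = factor(cohort$group, levels = c("NC", "SCZ")),
                 subject_id = cohort$subject_id),
            class = "feature_blocks")
}

# Covariate design: age, sex (M = 1), one-hot site, mean FD. Raw scale;
# continuous columns are standardized on the training rows at model time.
encode_covariates <- function(cohort) {
  site <- factor(cohort$site)
  oh <- vapply(levels(site), function(l) as.numeric(site == l),
               numeric(nrow(cohort)))
  oh <- matrix(oh, nrow = nrow(cohort),
               dimnames = list(NULL, paste0("site_", levels(site))))
  cbind(age = cohort$age,
        sex_M = as.numeric(cohort$sex == "M"),
        oh,
        mean_fd = cohort$mean_fd)
}

#' @method print feature_blocks
#' @export
print.feature_blocks <- function(x, ...) {
  cat("feature_blocks:", nrow(x$values), "subjects x", ncol(x$values),
      "features\n  blocks:",
      paste(sprintf("%s=%d", levels(x$block), table(x$block)), collapse = " "),
      "\n  covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Stratified train/holdout split
#'
#' Per class, a `holdout_fraction` share (rounded) of subjects is held out,
#' so the case/control ratio is preserved on both sides within rounding.
#'
#' @param features `feature_blocks`, or a factor/character label vector.
#' @param holdout_fraction Fraction held out (default 0.25).
#' @param seed RNG seed; identical seeds give identical splits.
#' @return List with integer row indices `train` and `holdout`.
#' @export
split_cohort <- function(features, holdout_fraction = 0.25, seed) {
  y <- if (inherits(features, "feature_blocks")) features$group else as.factor(features)
  stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  if (nlevels(droplevels(y)) != 2) stop("exactly two classes required")
  set.seed(as.integer(seed))
  holdout <- integer(0)
  for (lev in levels(droplevels(y))) {
    idx <- which(y == lev)
    n_h <- round(length(idx) * holdout_fraction)
    if (n_h < 1 || n_h >= length(idx)) {
      stop("class '", lev, "' would be absent from train or holdout")
    }
    holdout <- c(holdout, sort(sample(idx, n_h)))
  }
  holdout <- sort(holdout)
  list(train = setdiff(seq_along(y), holdout), holdout = holdout)
}

#' Blockwise PCA compression fitted on training rows
#'
#' Each feature block is decomposed separately (column-centered PCA fitted on
#' `train_rows` only). Per block the smallest number of components n >= 2
#' reaching `variance_target` cumulative explained variance is retained;
#' blocks named in `full_blocks` keep all components (default: the centroid-
#' dispersion block, whose 28 features are kept in full).
#'
#' @param features `feature_blocks`.
#' @param variance_target Cumulative variance fraction per block (default 0.20).
#' @param full_blocks Blocks exempt from truncation.
#' @param train_rows Integer rows used for fitting; nothing outside them
#'   touches the fitted means or axes.
#' @return Object of class `pca_block_model`; use [transform_blocks()] to
#'   project any row subset.
#' @export
fit_block_pca <- function(features, variance_target = 0.20,
                          full_blocks = "disp_cntr", train_rows) {
  stopifnot(inherits(features, "feature_blocks"),
            variance_target > 0, variance_target <= 1)
  models <- list()
  for (b in levels(features$block)) {
    cols <- which(features$block == b)
    x <- features$values[train_rows, cols, drop = FALSE]
    if (length(cols) < 2) {
      warning("block '", b, "' has < 2 features; keeping all unreduced")
      models[[b]] <- list(center = colMeans(x),
                          rotation = diag(1, length(cols), length(cols)),
                          variance_ratio = 1, n_components = length(cols),
                          cols = cols)
      next
    }
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    vr <- pc$sdev^2 / sum(pc$sdev^2)
    n_avail <- sum(pc$sdev > 1e-12)
    if (b %in% full_blocks) {
      nc <- min(length(cols), n_avail)
    } else {
      nc <- which(cumsum(vr) >= variance_target)[1]
      nc <- min(max(nc, 2L), n_avail)
    }
    models[[b]] <- list(center = pc$center,
                        rotation = pc$rotation[, seq_len(nc), drop = FALSE],
                        variance_ratio = vr[seq_len(nc)],
                        n_components = nc, cols = cols)
  }
  structure(list(blocks = models, variance_target = variance_target,
                 full_blocks = full_blocks), class = "pca_block_model")
}

#' Project feature rows onto the fitted block components
#'
#' @param model `pca_block_model` from [fit_block_pca()].
#' @param features The `feature_blocks` the model indexes into.
#' @param rows Row subset to transform (default all).
#' @return Matrix rows x components, columns named `<block>_pc<k>`, with a
#'   `block` attribute giving each component's block.
#' @export
transform_blocks <- function(model, features, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(features$values))
  parts <- lapply(names(model$blocks), function(b) {
    mb <- model$blocks[[b]]
    x <- features$values[rows, mb$cols, drop = FALSE]
    sc <- sweep(x, 2, mb$center) %*% mb$rotation
    colnames(sc) <- sprintf("%s_pc%d", b, seq_len(ncol(sc)))
    sc
  })
  out <- do.call(cbind, parts)
  attr(out, "block") <- rep(names(model$blocks),
                            vapply(model$blocks, function(m) m$n_components,
                                   numeric(1)))
  out
}

#' @method print pca_block_model
#' @export
print.pca_block_model <- function(x, ...) {
  nc <- vapply(x$blocks, function(m) m$n_components, numeric(1))
  cat("pca_block_model (variance target ", x$variance_target, "):\n", sep = "")
  for (b in names(nc)) {
    cat(sprintf("  %-10s %4d components (%.1f%% variance)\n", b, nc[b],
                100 * sum(x$blocks[[b]]$variance_ratio)))
  }
  invisible(x)
}
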