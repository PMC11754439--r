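# Multi-classifier benchmarking: top-importance feature selection, stratified
# 10-fold CV over the classifier suite with dummy baselines, feature-count
# sweeps with best-classifier densities, and rank-sum comparisons between
# feature types.

#' Select the features with the largest importance
#'
#' Deterministic: ties are broken by ascending feature index.
#'
#' @param importance Numeric importance vector (or the data.frame from
#'   [importance_to_feature_space()], optionally filtered with `scope`).
#' @param n Number of features to select; alternatively `fraction` of the
#'   available features (e.g. 0.01 for the top 1 percent).
#' @param scope Optional block name; restricts selection (and the fraction
#'   base) to that block when `importance` is a data.frame.
#' @param fraction Fraction of available features, used when `n` is missing.
#' @return Integer indices into the supplied importance vector (for a
#'   data.frame input: row indices of the full data.frame).
#' @export
select_top_features <- function(importance, n = NULL, scope = NULL,
                                fraction = NULL) {
  if (is.data.frame(importance)) {
    idx_all <- seq_len(nrow(importance))
    if (!is.null(scope)) idx_all <- idx_all[importance$block == scope]
    vals <- importance$importance[idx_all]
  } else {
    idx_all <- seq_along(importance)
    vals <- as.numeric(importance)
  }
  if (is.null(n)) {
    if (is.null(fraction)) stop("supply n or fraction")
    n <- round(fraction * length(vals))
  }
  if (n > length(vals)) {
    stop("requested ", n, " features but only ", length(vals), " available")
  }
  ord <- order(-vals, idx_all)
  idx_all[ord[seq_len(n)]]
}

# Fold-level preprocessing: drop near-constant columns, standardize
# continuous ones; fitted on the fold's training rows only.
fit_fold_prep <- function(x) {
  sds <- apply(x, 2, stats::sd)
  keep <- which(sds > 1e-10)
  if (length(keep) == 0) stop("no non-constant columns in fold")
  scaler <- fit_scaler(x[, keep, drop = FALSE])
  list(keep = keep, scaler = scaler)
}

apply_fold_prep <- function(prep, x) {
  apply_scaler(prep$scaler, x[, prep$keep, drop = FALSE])
}

#' Run the classifier suite on a feature subset
#'
#' Stratified k-fold cross-validation on the training rows; per fold, every
#' classifier is fitted on the fold-train rows (with preprocessing fitted
#' inside the fold) and scored on the fold-validation rows. Covariates are
#' always appended to the features. The best classifier (largest mean CV
#' accuracy; ties to the earlier suite entry) is refitted on the full
#' training set and scored on the holdout rows, alongside the dummy
#' baselines.
#'
#' @param x Subject-by-feature matrix (already subset to selected features).
#' @param labels Two-level factor (NC, SCZ); SCZ is the positive class for F1.
#' @param covariates Covariate design matrix, same rows as `x`.
#' @param train_rows,holdout_rows Row indices.
#' @param classifiers Named suite (default [classifier_suite()]).
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for fold assignment and stochastic learners.
#' @param keep_predictions Also return each classifier's pooled out-of-fold
#'   CV predictions (for permutation-null diagnostics such as
#'   [chance_band()]).
#' @return Object of class `benchmark_result`: `cv` (classifier x fold long
#'   table), `summary` (per-classifier mean CV metrics), `best_classifier`,
#'   `holdout` (best-classifier holdout metrics), `baselines`; with
#'   `keep_predictions`, also `cv_predictions` (list per classifier, aligned
#'   with `cv_truth`).
#' @export
run_classifier_suite <- function(x, labels, covariates, train_rows,
                                 holdout_rows, classifiers = NULL,
                                 folds = 10, seed = 1,
                                 keep_predictions = FALSE) {
  if (is.null(classifiers)) classifiers <- classifier_suite(seed)
  labels <- factor(labels, levels = c("NC", "SCZ"))
  pos <- "SCZ"
  xx <- cbind(as.matrix(x), as.matrix(covariates))
  cn <- colnames(xx)
  if (is.null(cn)) cn <- rep("", ncol(xx))
  cn[cn == "" | is.na(cn)] <- sprintf("V%d", which(cn == "" | is.na(cn)))
  colnames(xx) <- make.names(cn, unique = TRUE)
  y_tr <- labels[train_rows]
  fold_of <- make_stratified_folds(y_tr, folds, seed)
  cv <- list()
  pooled <- if (keep_predictions) {
    stats::setNames(rep(list(factor(rep(NA, length(train_rows)),
                                    levels = levels(labels))),
                        length(classifiers)), names(classifiers))
  } else NULL
  for (f in seq_len(folds)) {
    tr <- train_rows[fold_of != f]
    va <- train_rows[fold_of == f]
    if (nlevels(droplevels(labels[va])) < 2 || nlevels(droplevels(labels[tr])) < 2) {
      stop("fold ", f, " lost a class; use fewer folds")
    }
    prep <- fit_fold_prep(xx[tr, , drop = FALSE])
    xtr <- apply_fold_prep(prep, xx[tr, , drop = FALSE])
    xva <- apply_fold_prep(prep, xx[va, , drop = FALSE])
    for (cl in names(classifiers)) {
      m <- classifiers[[cl]]$fit(xtr, labels[tr])
      pred <- classifiers[[cl]]$predict(m, xva)
      if (keep_predictions) pooled[[cl]][fold_of == f] <- pred
      cv[[length(cv) + 1]] <- data.frame(
        classifier = cl, fold = f,
        accuracy = accuracy_score(labels[va], pred),
        f1 = f1_score(labels[va], pred, pos), stringsAsFactors = FALSE)
    }
  }
  cv <- do.call(rbind, cv)
  summary <- do.call(rbind, lapply(names(classifiers), function(cl) {
    s <- cv[cv$classifier == cl, ]
    data.frame(classifier = cl, mean_cv_accuracy = mean(s$accuracy),
               mean_cv_f1 = mean(s$f1), stringsAsFactors = FALSE)
  }))
  best <- summary$classifier[which.max(summary$mean_cv_accuracy)]

  prep <- fit_fold_prep(xx[train_rows, , drop = FALSE])
  xtr <- apply_fold_prep(prep, xx[train_rows, , drop = FALSE])
  xho <- apply_fold_prep(prep, xx[holdout_rows, , drop = FALSE])
  m <- classifiers[[best]]$fit(xtr, y_tr)
  pred_ho <- classifiers[[best]]$predict(m, xho)
  holdout <- list(accuracy = accuracy_score(labels[holdout_rows], pred_ho),
                  f1 = f1_score(labels[holdout_rows], pred_ho, pos))

  baselines <- lapply(c(majority = "majority", uniform = "uniform"),
                      function(strat) {
    d <- dummy_classifier(strat, seed)
    dm <- d$fit(xtr, y_tr)
    pd <- d$predict(dm, xho)
    list(accuracy = accuracy_score(labels[holdout_rows], pd),
         f1 = f1_score(labels[holdout_rows], pd, pos))
  })

  structure(c(list(cv = cv, summary = summary, best_classifier = best,
                   holdout = holdout, baselines = baselines,
                   folds = folds, positive = pos),
              if (keep_predictions) list(cv_predictions = pooled,
                                         cv_truth = y_tr)),
            class = "benchmark_result")
}

#' @method print benchmark_result
#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark_result:", x$folds, "-fold CV over",
      nrow(x$summary), "classifiers\n")
  s <- x$summary[order(-x$summary$mean_cv_accuracy), ]
  for (r in seq_len(min(5, nrow(s)))) {
    cat(sprintf("  %-6s CV acc %.3f  CV F1 %.3f\n", s$classifier[r],
                s$mean_cv_accuracy[r], s$mean_cv_f1[r]))
  }
  cat(sprintf("  best: %s | holdout acc %.3f F1 %.3f | majority baseline acc %.3f F1 %.3f\n",
              x$best_classifier, x$holdout$accuracy, x$holdout$f1,
              x$baselines$majority$accuracy, x$baselines$majority$f1))
  invisible(x)
}

#' Sweep feature counts and feature types through the suite
#'
#' One suite run per (feature type, count); the best-classifier density is,
#' per classifier, the fraction of runs in which it had the highest mean CV
#' accuracy (densities sum to 1).
#'
#' @param feature_importance data.frame from [importance_to_feature_space()].
#' @param features `feature_blocks`.
#' @param counts Sorted feature counts (e.g. 100 to 10,000 at full scale).
#' @param types Feature types to sweep: block names and/or `"mixed"`
#'   (selection over all blocks pooled).
#' @param train_rows,holdout_rows,folds,seed As in [run_classifier_suite()].
#' @param classifiers Optional suite override.
#' @return List with `runs` (data.frame: type, count, best classifier,
#'   holdout metrics), `results` (named list of `benchmark_result`), and
#'   `density` (named numeric, sums to 1).
#' @export
sweep_feature_counts <- function(feature_importance, features, counts,
                                 types = c("conn", "grad", "disp_nbr",
                                           "disp_cntr", "mixed"),
                                 train_rows, holdout_rows, folds = 10,
                                 seed = 1, classifiers = NULL) {
  if (is.unsorted(counts)) stop("counts must be sorted ascending")
  if (is.null(classifiers)) classifiers <- classifier_suite(seed)
  runs <- list(); results <- list()
  for (ty in types) {
    scope <- if (ty == "mixed") NULL else ty
    avail <- if (is.null(scope)) nrow(feature_importance) else
      sum(feature_importance$block == scope)
    for (cnt in counts) {
      if (cnt > avail) stop("count ", cnt, " exceeds available features (",
                            avail, ") for type ", ty)
      idx <- select_top_features(feature_importance, n = cnt, scope = scope)
      res <- run_classifier_suite(features$values[, idx, drop = FALSE],
                                  features$group, features$covariates,
                                  train_rows, holdout_rows,
                                  classifiers = classifiers,
                                  folds = folds, seed = seed)
      key <- paste(ty, cnt, sep = "_")
      results[[key]] <- res
      runs[[key]] <- data.frame(type = ty, count = cnt,
                                best = res$best_classifier,
                                holdout_accuracy = res$holdout$accuracy,
                                holdout_f1 = res$holdout$f1,
                                stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, runs)
  density <- table(factor(runs$best, levels = names(classifiers)))
  density <- as.numeric(density) / nrow(runs)
  names(density) <- names(classifiers)
  list(runs = runs, results = results, density = density)
}

#' Rank-sum comparison of feature types against a reference type
#'
#' Two-sided Mann-Whitney U tests of per-classifier metric vectors, reference
#' type (connectivity) versus every other supplied type, flagged at a
#' Bonferroni-style alpha (default 0.01 = 0.05 / 5 comparisons). Exact
#' p-values are used when there are no ties (the small-sample regime of 13
#' classifiers); a normal approximation with tie correction otherwise.
#'
#' @param metrics Named list of equal-length numeric vectors (one entry per
#'   classifier, dummies excluded), or a data.frame/matrix with one column
#'   per feature type.
#' @param reference Name of the reference type (default `"conn"`).
#' @param alpha Significance threshold after correction (default 0.01).
#' @return data.frame of class `comparison_table`: contrast, U, p,
#'   significant.
#' @export
compare_feature_types <- function(metrics, reference = "conn", alpha = 0.01) {
  if (is.matrix(metrics) || is.data.frame(metrics)) {
    metrics <- as.list(as.data.frame(metrics))
  }
  if (!reference %in% names(metrics)) {
    stop("reference type '", reference, "' not in metrics")
  }
  ref <- metrics[[reference]]
  if (length(ref) < 3) stop("metric vectors must have length >= 3")
  others <- setdiff(names(metrics), reference)
  out <- do.call(rbind, lapply(others, function(ty) {
    y <- metrics[[ty]]
    if (length(y) != length(ref)) stop("unequal metric vector lengths")
    wt <- suppressWarnings(stats::wilcox.test(ref, y, alternative = "two.sided",
                                              exact = NULL, correct = TRUE))
    data.frame(contrast = paste(reference, "vs", ty),
               U = unname(wt$statistic), p = wt$p.value,
               significant = wt$p.value <= alpha, stringsAsFactors = FALSE)
  }))
  attr(out, "alpha") <- alpha
  class(out) <- c("comparison_table", class(out))
  out
}

#' Permutation chance band for an accuracy given fixed predictions
#'
#' Under label exchangeability (no signal), a classifier's accuracy is
#' determined by how its prediction margins pair with permuted labels. The
#' band is the central `level` interval of accuracies over `B` label
#' permutations; an observed accuracy outside it indicates signal (or
#' leakage).
#'
#' @param pred Predicted classes.
#' @param truth True classes.
#' @param B Number of permutations.
#' @param level Band coverage (default 0.95).
#' @param seed RNG seed.
#' @return List with `lower`, `upper`, `observed`.
#' @export
chance_band <- function(pred, truth, B = 2000, level = 0.95, seed = 1) {
  pred <- as.character(pred); truth <- as.character(truth)
  set.seed(as.integer(seed))
  null_acc <- replicate(B, mean(pred == truth[sample.int(length(truth))]))
  qs <- stats::quantile(null_acc, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(lower = qs[1], upper = qs[2], observed = mean(pred == truth))
}
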