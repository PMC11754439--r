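# L2-logistic classification on block components plus covariates, holdout
# permutation component importance, and inverse projection of importances to
# raw feature space.

# Train-fitted standardizer for the continuous columns of a design matrix.
# Binary/one-hot columns pass through untouched.
fit_scaler <- function(x, continuous = NULL) {
  if (is.null(continuous)) {
    continuous <- apply(x, 2, function(v) length(unique(v)) > 2)
  }
  center <- ifelse(continuous, colMeans(x), 0)
  scale <- ifelse(continuous, apply(x, 2, stats::sd), 1)
  scale[scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, `/`)
}

#' Fit the importance-stage L2-logistic classifier
#'
#' Ridge-penalized logistic regression (penalty strength 1, i.e. lambda =
#' 1/n_train in glmnet's scaling) on the block components plus covariates.
#' Components and continuous covariates are standardized using training rows
#' only; covariates are never PCA-compressed.
#'
#' @param components Matrix from [transform_blocks()] (all rows).
#' @param covariates Covariate design matrix (all rows).
#' @param labels Factor with levels NC, SCZ.
#' @param train_rows Training row indices.
#' @param lambda Ridge penalty; default `1 / length(train_rows)`.
#' @return Object of class `importance_model` carrying coefficients, the
#'   scaler, and column bookkeeping (which columns are permutable components).
#' @export
fit_importance_model <- function(components, covariates, labels, train_rows,
                                 lambda = NULL) {
  x <- cbind(components, covariates)
  comp_cols <- seq_len(ncol(components))
  scaler <- fit_scaler(x[train_rows, , drop = FALSE])
  xs <- apply_scaler(scaler, x)
  if (is.null(lambda)) lambda <- 1 / length(train_rows)
  fit <- glmnet::glmnet(xs[train_rows, , drop = FALSE],
                        labels[train_rows], family = "binomial",
                        alpha = 0, lambda = lambda, standardize = FALSE,
                        thresh = 1e-10)
  beta <- as.numeric(fit$beta)
  structure(list(beta = beta, intercept = as.numeric(fit$a0),
                 scaler = scaler, comp_cols = comp_cols,
                 comp_block = attr(components, "block"),
                 colnames = colnames(x),
                 levels = levels(labels), lambda = lambda),
            class = "importance_model")
}

# Linear predictor and class prediction on already-assembled design rows.
predict_linear <- function(model, x) {
  xs <- apply_scaler(model$scaler, x)
  drop(xs %*% model$beta) + model$intercept
}

#' @export
predict.importance_model <- function(object, newdata, ...) {
  eta <- predict_linear(object, newdata)
  factor(ifelse(eta > 0, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' Permutation component importance on the holdout set
#'
#' For every component column, the holdout column is shuffled `n_perm` times;
#' each shuffle's importance sample is baseline accuracy minus permuted
#' accuracy. Covariate columns are never shuffled. Each component uses its
#' own RNG stream derived from `seed`, so results are reproducible regardless
#' of evaluation order.
#'
#' @param model `importance_model`.
#' @param components,covariates Full design (all rows).
#' @param labels Outcome factor.
#' @param holdout_rows Holdout row indices.
#' @param n_perm Permutations per component (default 1000; the full-scale
#'   setting is 10,000).
#' @param seed RNG seed.
#' @return Object of class `importance_report`: data.frame
#'   `component_importance` (component, block, mean, sd), `baseline_accuracy`,
#'   `n_perm`.
#' @export
permutation_component_importance <- function(model, components, covariates,
                                             labels, holdout_rows,
                                             n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  x <- cbind(components, covariates)[holdout_rows, , drop = FALSE]
  y <- labels[holdout_rows]
  xs <- apply_scaler(model$scaler, x)
  eta <- drop(xs %*% model$beta) + model$intercept
  pred_acc <- function(e) mean((e > 0) == (y == model$levels[2]))
  baseline <- pred_acc(eta)
  nh <- length(holdout_rows)
  comp <- model$comp_cols
  means <- sds <- numeric(length(comp))
  for (jj in seq_along(comp)) {
    j <- comp[jj]
    bj <- model$beta[j]
    set.seed(as.integer(seed) + jj - 1L)
    drops <- numeric(n_perm)
    if (bj == 0) {
      # permuting a zero-coefficient column cannot change predictions
      drops[] <- 0
    } else {
      xj <- xs[, j]
      contrib <- bj * xj
      for (pp in seq_len(n_perm)) {
        e <- eta - contrib + bj * xj[sample.int(nh)]
        drops[pp] <- baseline - pred_acc(e)
      }
    }
    means[jj] <- mean(drops)
    sds[jj] <- stats::sd(drops)
  }
  structure(list(
    component_importance = data.frame(
      component = model$colnames[comp],
      block = model$comp_block,
      mean = means, sd = sds, stringsAsFactors = FALSE),
    baseline_accuracy = baseline, n_perm = n_perm),
    class = "importance_report")
}

#' @method print importance_report
#' @export
print.importance_report <- function(x, ...) {
  cat("importance_report: baseline holdout accuracy ",
      sprintf("%.3f", x$baseline_accuracy), ", n_perm = ", x$n_perm, "\n",
      sep = "")
  agg <- tapply(x$component_importance$mean, x$component_importance$block, mean)
  for (b in names(agg)) cat(sprintf("  %-10s mean importance %.4f\n", b, agg[b]))
  invisible(x)
}

#' Inverse-project component importances to raw features
#'
#' Per block, feature importance is `|W i|` where `W` (features x components)
#' is the block's PCA axis matrix and `i` the vector of mean component
#' importances: the unsigned linear back-projection through the fitted
#' projection, with no mean re-addition. `signed = TRUE` skips the absolute
#' value.
#'
#' @param report `importance_report`.
#' @param pca `pca_block_model` the components came from.
#' @param signed Keep the sign of the back-projection (default FALSE).
#' @return data.frame with columns `feature`, `block`, `importance`, in
#'   feature-matrix column order.
#' @export
importance_to_feature_space <- function(report, pca, signed = FALSE) {
  ci <- report$component_importance
  out <- lapply(names(pca$blocks), function(b) {
    mb <- pca$blocks[[b]]
    i_b <- ci$mean[ci$block == b]
    if (length(i_b) != mb$n_components) {
      stop("block '", b, "': ", length(i_b), " importances vs ",
           mb$n_components, " components")
    }
    v <- drop(mb$rotation %*% i_b)
    if (!signed) v <- abs(v)
    data.frame(feature = rownames(mb$rotation), block = b, importance = v,
               col = mb$cols, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$col), c("feature", "block", "importance")]
  rownames(out) <- NULL
  out
}
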