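# The thirteen-classifier suite. Each entry is fit(x, y) -> model and
# predict(model, x) -> factor; x is an already-standardized numeric matrix
# (preprocessing is fitted within each CV fold, never on validation rows).
#
# Library-backed where a stock implementation exists (glmnet, class, e1071,
# rpart, randomForest, ranger, xgboost, MASS); AdaBoost (discrete SAMME over
# depth-1 rpart stumps) and regularized QDA (ridge-shrunk class covariances)
# are implemented here.

xgb_fit <- function(x, y, params, nrounds) {
  d <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
  m <- xgboost::xgb.train(params = params, data = d, nrounds = nrounds,
                          verbose = 0)
  attr(m, "levels") <- levels(y)
  m
}

xgb_predict <- function(model, x, levels) {
  pr <- predict(model, xgboost::xgb.DMatrix(x))
  factor(ifelse(pr > 0.5, levels[2], levels[1]), levels = levels)
}

# Discrete AdaBoost (SAMME) with decision stumps.
fit_adaboost <- function(x, y, n_rounds = 50) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- as.data.frame(x)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = y), weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5) break
    alpha <- if (err <= 1e-10) 10 else 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_adaboost <- function(model, x) {
  df <- as.data.frame(x)
  lv <- model$levels
  if (length(model$stumps) == 0) {
    return(factor(rep(lv[1], nrow(df)), levels = lv))
  }
  score <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[m]], df, type = "class")
    score <- score + model$alphas[m] * ifelse(pred == lv[2], 1, -1)
  }
  factor(ifelse(score > 0, lv[2], lv[1]), levels = lv)
}

# Gaussian discriminant with ridge-shrunk class covariances: Sigma_k +
# reg * mean(diag(Sigma_k)) * I, so the rule is defined even when features
# outnumber class members or are collinear.
fit_rqda <- function(x, y, reg = 0.01) {
  lv <- levels(y)
  cls <- lapply(lv, function(l) {
    xi <- x[y == l, , drop = FALSE]
    mu <- colMeans(xi)
    s <- stats::cov(xi)
    if (anyNA(s)) s <- matrix(0, ncol(x), ncol(x))
    ridge <- reg * max(mean(diag(s)), 1e-8)
    s <- s + diag(ridge, ncol(x))
    ch <- chol(s)
    list(mu = mu, chol = ch,
         logdet = 2 * sum(log(diag(ch))),
         logprior = log(mean(y == l)))
  })
  names(cls) <- lv
  list(classes = cls, levels = lv)
}

predict_rqda <- function(model, x) {
  lv <- model$levels
  scores <- vapply(model$classes, function(cl) {
    d <- sweep(x, 2, cl$mu)
    z <- backsolve(cl$chol, t(d), transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * cl$logdet + cl$logprior
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  factor(lv[max.col(scores, ties.method = "first")], levels = lv)
}

#' The named classifier suite
#'
#' Thirteen classifiers with library-default hyperparameters and fixed seeds:
#' `lr` (L2 logistic), `kn` (k-nearest neighbors, k = 5), `nb` (Gaussian
#' naive Bayes), `dt` (decision tree), `svm` (RBF support vector machine),
#' `ridge` (least-squares ridge on +/-1 targets), `rf` (random forest), `ab`
#' (AdaBoost stumps), `gb` (gradient-boosted trees, depth-wise), `lgb`
#' (gradient-boosted trees, histogram + leaf-wise growth), `lda` (linear
#' discriminant), `et` (extremely randomized trees), `qda` (regularized
#' quadratic discriminant). The two dummies, `dummy_majority` and
#' `dummy_uniform`, are baselines, not suite members.
#'
#' @param seed Seed used by the stochastic learners.
#' @return Named list of `list(fit, predict)` pairs.
#' @export
classifier_suite <- function(seed = 1) {
  seed <- as.integer(seed)
  list(
    lr = list(
      fit = function(x, y) glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                                          lambda = 1 / nrow(x),
                                          standardize = FALSE, thresh = 1e-10),
      predict = function(m, x) {
        factor(drop(predict(m, x, type = "class")), levels = m$classnames)
      }),
    kn = list(
      fit = function(x, y) list(x = x, y = y),
      predict = function(m, x) {
        factor(as.character(class::knn(m$x, x, m$y, k = 5)), levels = levels(m$y))
      }),
    nb = list(
      fit = function(x, y) e1071::naiveBayes(x, y),
      predict = function(m, x) predict(m, x)),
    dt = list(
      fit = function(x, y) {
        rpart::rpart(y ~ ., data = data.frame(x, y = y), method = "class",
                     control = rpart::rpart.control(xval = 0))
      },
      predict = function(m, x) predict(m, data.frame(x), type = "class")),
    svm = list(
      fit = function(x, y) e1071::svm(x, y, kernel = "radial", scale = FALSE),
      predict = function(m, x) predict(m, x)),
    ridge = list(
      fit = function(x, y) {
        list(fit = glmnet::glmnet(x, as.numeric(y == levels(y)[2]) * 2 - 1,
                                  family = "gaussian", alpha = 0,
                                  lambda = 1 / nrow(x), standardize = FALSE),
             levels = levels(y))
      },
      predict = function(m, x) {
        factor(ifelse(drop(predict(m$fit, x)) > 0, m$levels[2], m$levels[1]),
               levels = m$levels)
      }),
    rf = list(
      fit = function(x, y) {
        set.seed(seed)
        randomForest::randomForest(x, y, ntree = 500)
      },
      predict = function(m, x) predict(m, x)),
    ab = list(
      fit = function(x, y) fit_adaboost(x, y),
      predict = predict_adaboost),
    gb = list(
      fit = function(x, y) xgb_fit(x, y, list(objective = "binary:logistic",
                                              max_depth = 3, eta = 0.1,
                                              seed = seed), nrounds = 100),
      predict = function(m, x) xgb_predict(m, x, attr(m, "levels"))),
    lgb = list(
      fit = function(x, y) xgb_fit(x, y, list(objective = "binary:logistic",
                                              tree_method = "hist",
                                              grow_policy = "lossguide",
                                              max_leaves = 31, max_depth = 0,
                                              eta = 0.1, seed = seed),
                                   nrounds = 100),
      predict = function(m, x) xgb_predict(m, x, attr(m, "levels"))),
    lda = list(
      fit = function(x, y) suppressWarnings(MASS::lda(x, grouping = y)),
      predict = function(m, x) predict(m, x)$class),
    et = list(
      fit = function(x, y) ranger::ranger(y = y, x = data.frame(x),
                                          num.trees = 500,
                                          splitrule = "extratrees",
                                          num.random.splits = 1,
                                          seed = seed),
      predict = function(m, x) predict(m, data.frame(x))$predictions),
    qda = list(
      fit = function(x, y) fit_rqda(x, y),
      predict = predict_rqda)
  )
}

#' Dummy baseline classifiers
#'
#' `majority` always predicts the most frequent training class (accuracy =
#' majority rate, minority-class F1 = 0); `uniform` predicts uniformly at
#' random.
#'
#' @param strategy `"majority"` or `"uniform"`.
#' @param seed Seed for the uniform dummy.
#' @return A `list(fit, predict)` pair like [classifier_suite()] entries.
#' @export
dummy_classifier <- function(strategy = c("majority", "uniform"), seed = 1) {
  strategy <- match.arg(strategy)
  if (strategy == "majority") {
    list(
      fit = function(x, y) {
        list(cls = names(which.max(table(y))), levels = levels(y))
      },
      predict = function(m, x) factor(rep(m$cls, nrow(x)), levels = m$levels))
  } else {
    list(
      fit = function(x, y) list(levels = levels(y)),
      predict = function(m, x) {
        set.seed(as.integer(seed))
        factor(sample(m$levels, nrow(x), replace = TRUE), levels = m$levels)
      })
  }
}
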