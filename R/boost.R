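#' Stratified K-fold assignment
#'
#' Shuffles within each class and deals samples round-robin so every fold
#' preserves the class proportions as closely as integer counts allow.
#'
#' @param labels 0/1 integer label vector.
#' @param K Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer fold id (1..K) per sample.
#' @export
stratified_folds <- function(labels, K = 10L, seed = 1L) {
  stopifnot(K >= 2)
  if (min(table(labels)) < K)
    stop("stratification error: a class has fewer than K samples")
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(K), length(idx))
    }
  })
  fold
}

#' Default hyperparameter search bounds
#'
#' Six tuned dimensions of the tree booster: learning rate `eta`, maximum
#' tree depth, number of boosting rounds, row subsample fraction, column
#' subsample fraction, and minimum child weight. Depth and rounds are
#' treated as continuous during the search and rounded at evaluation time.
#'
#' @param nrounds_max Upper bound on boosting rounds (default 150).
#' @return 2 x 6 matrix (row 1 lower, row 2 upper) with named columns.
#' @export
default_search_bounds <- function(nrounds_max = 150) {
  rbind(lower = c(eta = 0.01, max_depth = 1, nrounds = 10,
                  subsample = 0.5, colsample_bytree = 0.5,
                  min_child_weight = 1),
        upper = c(eta = 0.3, max_depth = 6, nrounds = nrounds_max,
                  subsample = 1, colsample_bytree = 1,
                  min_child_weight = 10))
}

#' Search configuration for the selection loop
#'
#' @param n1 Random initialization evaluations per iteration (default 10).
#' @param n2 Sequential GP-UCB evaluations per iteration (default 25).
#' @param K Cross-validation folds (default 10).
#' @param bounds Hyperparameter bounds matrix (default
#'   [default_search_bounds()]).
#' @param ucb_kappa UCB exploration weight (default 2).
#' @param seed Integer seed (default 1).
#' @return A `search_config` list.
#' @export
search_config <- function(n1 = 10L, n2 = 25L, K = 10L,
                          bounds = default_search_bounds(),
                          ucb_kappa = 2, seed = 1L) {
  stopifnot(n1 >= 1, n2 >= 0, K >= 2)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), K = as.integer(K),
                 bounds = as.matrix(bounds), ucb_kappa = ucb_kappa,
                 seed = as.integer(seed)),
            class = "search_config")
}

point_to_params <- function(point) {
  list(objective = "binary:logistic", eval_metric = "logloss",
       nthread = 1, seed = 1,
       eta = unname(point[["eta"]]),
       max_depth = as.integer(round(point[["max_depth"]])),
       subsample = unname(point[["subsample"]]),
       colsample_bytree = unname(point[["colsample_bytree"]]),
       min_child_weight = unname(point[["min_child_weight"]]))
}

binary_logloss <- function(y, p) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

fit_booster <- function(x, y, point) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(params = point_to_params(point), data = dtrain,
                     nrounds = as.integer(round(point[["nrounds"]])),
                     verbose = 0)
}

gain_importance <- function(model, feature_names) {
  imp <- stats::setNames(rep(0, length(feature_names)), feature_names)
  tab <- tryCatch(xgboost::xgb.importance(model = model),
                  error = function(e) NULL)
  if (!is.null(tab) && nrow(tab))
    imp[tab$Feature] <- imp[tab$Feature] + tab$Gain
  imp
}

#' Cross-validated log-loss and mean gain importance
#'
#' Stratified K-fold cross-validation of a gradient-boosted tree binary
#' classifier at one hyperparameter point: per fold, fit on the training
#' folds, score the held-out log-loss, and extract per-feature gain
#' importance; returns the fold-mean log-loss and the importance averaged
#' over the K fitted models (features never used in any split have
#' importance 0).
#'
#' @param features Samples x features numeric matrix.
#' @param labels 0/1 labels.
#' @param point Named hyperparameter vector (see [default_search_bounds()]).
#' @param K Folds (default 10); ignored when `folds` is supplied.
#' @param seed Fold-assignment seed; ignored when `folds` is supplied.
#' @param folds Optional precomputed fold id vector, so that log-loss
#'   comparisons between points are paired on the same folds.
#' @return List with `logloss` (mean held-out log-loss) and `importance`
#'   (named mean gain vector).
#' @export
cv_logloss_and_importance <- function(features, labels, point, K = 10L,
                                      seed = 1L, folds = NULL) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (is.null(folds)) folds <- stratified_folds(labels, K, seed)
  ks <- sort(unique(folds))
  ll <- numeric(length(ks))
  imp <- matrix(0, length(ks), ncol(features),
                dimnames = list(NULL, colnames(features)))
  for (i in seq_along(ks)) {
    te <- folds == ks[i]
    if (length(unique(labels[!te])) < 2)
      stop("stratification error: a class is absent from a training fold")
    model <- fit_booster(features[!te, , drop = FALSE], labels[!te], point)
    p <- predict(model, xgboost::xgb.DMatrix(features[te, , drop = FALSE],
                                             nthread = 1))
    ll[i] <- binary_logloss(labels[te], p)
    imp[i, ] <- gain_importance(model, colnames(features))
  }
  list(logloss = mean(ll), importance = colMeans(imp))
}

#' Remove the minimum-importance features
#'
#' Drops every feature whose mean importance lies within `tolerance`
#' (relative to the importance range) of the minimum; remaining features
#' keep their original order. When all importances are equal the result is
#' empty, which terminates the selection loop.
#'
#' @param feature_names Character vector.
#' @param importances Aligned numeric vector (non-negative).
#' @param tolerance Relative tie tolerance (default 1e-12).
#' @return Character vector of surviving feature names.
#' @export
eliminate_min_importance <- function(feature_names, importances,
                                     tolerance = 1e-12) {
  stopifnot(length(feature_names) == length(importances))
  lo <- min(importances)
  scale <- max(max(importances) - lo, max(abs(importances)), 1)
  feature_names[importances - lo > tolerance * scale]
}

#' Confusion-matrix classification metrics
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return List with precision (`NA` when no positive calls), accuracy,
#'   balanced_accuracy, sensitivity, specificity.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       accuracy = (tp + tn) / (tp + fp + tn + fn),
       balanced_accuracy = (sens + spec) / 2,
       sensitivity = sens, specificity = spec)
}

#' Cross-validated evaluation of a feature subset at a hyperparameter point
#'
#' Stratified K-fold evaluation: per fold, fit on the training folds,
#' predict held-out probabilities, classify at `threshold`. Reports pooled
#' confusion counts and metrics (the primary figures) plus per-fold metrics
#' and their across-fold averages; folds with no positive calls have
#' undefined precision and are excluded from the precision fold average.
#'
#' @param features Samples x features matrix.
#' @param labels 0/1 labels.
#' @param feature_subset Character vector of columns to use.
#' @param point Named hyperparameter vector.
#' @param K Folds (default 10).
#' @param seed Fold seed (default 1).
#' @param threshold Probability threshold for the positive class
#'   (default 0.5).
#' @return An `evaluation_report`: list with `confusion` (tp, fp, tn, fn),
#'   `pooled` metrics, `fold_mean` metrics and `per_fold` data frame.
#' @export
evaluate_model <- function(features, labels, feature_subset, point,
                           K = 10L, seed = 1L, threshold = 0.5) {
  stopifnot(length(feature_subset) >= 1)
  x <- features[, feature_subset, drop = FALSE]
  folds <- stratified_folds(labels, K, seed)
  per <- lapply(sort(unique(folds)), function(k) {
    te <- folds == k
    model <- fit_booster(x[!te, , drop = FALSE], labels[!te], point)
    p <- predict(model, xgboost::xgb.DMatrix(x[te, , drop = FALSE],
                                             nthread = 1))
    yhat <- as.integer(p >= threshold)
    y <- labels[te]
    c(fold = k,
      tp = sum(yhat == 1 & y == 1), fp = sum(yhat == 1 & y == 0),
      tn = sum(yhat == 0 & y == 0), fn = sum(yhat == 0 & y == 1))
  })
  per <- as.data.frame(do.call(rbind, per))
  fm <- lapply(seq_len(nrow(per)), function(i)
    confusion_metrics(per$tp[i], per$fp[i], per$tn[i], per$fn[i]))
  per$precision <- vapply(fm, `[[`, 0, "precision")
  per$accuracy <- vapply(fm, `[[`, 0, "accuracy")
  per$balanced_accuracy <- vapply(fm, `[[`, 0, "balanced_accuracy")
  pooled <- confusion_metrics(sum(per$tp), sum(per$fp),
                              sum(per$tn), sum(per$fn))
  structure(list(
    confusion = c(tp = sum(per$tp), fp = sum(per$fp),
                  tn = sum(per$tn), fn = sum(per$fn)),
    pooled = pooled,
    fold_mean = list(
      precision = mean(per$precision, na.rm = TRUE),
      accuracy = mean(per$accuracy),
      balanced_accuracy = mean(per$balanced_accuracy)),
    per_fold = per,
    threshold = threshold
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cm <- x$confusion
  cat("<evaluation_report> pooled confusion: TP", cm["tp"], "FP", cm["fp"],
      "TN", cm["tn"], "FN", cm["fn"], "\n")
  cat(sprintf("  precision %.3f | accuracy %.3f | balanced accuracy %.3f\n",
              x$pooled$precision, x$pooled$accuracy,
              x$pooled$balanced_accuracy))
  invisible(x)
}
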