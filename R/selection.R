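#' Bayesian hyperparameter optimization of the cross-validated classifier
#'
#' Runs GP-UCB Bayesian optimization of the K-fold cross-validated log-loss
#' over the hyperparameter box: `n1` random points, then every supplied
#' probe point (previous iterations' optima), then `n2` sequential UCB
#' acquisitions; returns the argmin over all evaluations. One fold
#' assignment (from `folds` or the config seed) is shared by every
#' evaluation so comparisons are paired.
#'
#' @param features Samples x features matrix.
#' @param labels 0/1 labels.
#' @param config A [search_config()].
#' @param probe_points List of named hyperparameter vectors to probe.
#' @param folds Optional precomputed fold ids.
#' @return List with `best_point`, `best_loss`, `history`.
#' @export
bayes_optimize <- function(features, labels, config = search_config(),
                           probe_points = list(), folds = NULL) {
  if (is.null(folds))
    folds <- stratified_folds(labels, config$K, config$seed)
  objective <- function(point)
    cv_logloss_and_importance(features, labels, point,
                              folds = folds)$logloss
  optimize_loss_ucb(objective, config$bounds, n1 = config$n1,
                    n2 = config$n2, ucb_kappa = config$ucb_kappa,
                    probe_points = probe_points, seed = config$seed)
}

#' Recursive feature elimination with embedded Bayesian optimization
#'
#' The model-selection loop: starting from all features, each iteration
#' (1) re-runs Bayesian optimization of the cross-validated log-loss over
#' the hyperparameter box, probing every previous iteration's optimum in
#' addition to fresh random and UCB points, (2) averages per-feature gain
#' importance over the K fold models at the iteration's best point, and
#' (3) removes every feature tied at the minimum importance. The loop stops
#' when one feature remains, when all importances are equal, or when the
#' next feature set would be empty. The returned selection is the
#' (feature set, hyperparameter point) pair attaining the minimum
#' cross-validated log-loss across all iterations, refit and evaluated.
#'
#' @param features Samples x features matrix (>= 2 columns).
#' @param labels 0/1 labels.
#' @param config A [search_config()].
#' @param threshold Classification threshold for the final evaluation
#'   (default 0.5).
#' @return A `selection_result`: list with `trajectory` (data frame:
#'   iteration, n_features, logloss, features, best hyperparameters),
#'   `iterations` (full per-iteration records), `selected_features`,
#'   `selected_point`, `selected_logloss`, and `evaluation`
#'   (an `evaluation_report`).
#' @export
run_selection_loop <- function(features, labels, config = search_config(),
                               threshold = 0.5) {
  stopifnot(is.matrix(features), ncol(features) >= 2)
  current <- colnames(features)
  probes <- list()
  iters <- list()
  l <- 0L
  repeat {
    l <- l + 1L
    iter_seed <- config$seed + 7919L * l
    folds <- stratified_folds(labels, config$K, iter_seed)
    iter_cfg <- config
    iter_cfg$seed <- iter_seed
    x <- features[, current, drop = FALSE]
    bo <- bayes_optimize(x, labels, iter_cfg, probe_points = probes,
                         folds = folds)
    fit <- cv_logloss_and_importance(x, labels, bo$best_point, folds = folds)
    iters[[l]] <- list(l = l, feature_set = current,
                       best_point = bo$best_point, logloss = bo$best_loss,
                       importances = fit$importance)
    probes <- c(probes, list(bo$best_point))
    if (length(current) == 1L) break
    nxt <- eliminate_min_importance(current, fit$importance)
    if (length(nxt) == 0L || length(nxt) == length(current)) break
    current <- nxt
  }
  logloss <- vapply(iters, `[[`, 0, "logloss")
  k <- which.min(logloss)
  selected <- iters[[k]]
  evaluation <- evaluate_model(features, labels, selected$feature_set,
                               selected$best_point, K = config$K,
                               seed = config$seed, threshold = threshold)
  traj <- data.frame(
    iteration = vapply(iters, `[[`, 0L, "l"),
    n_features = vapply(iters, function(it) length(it$feature_set), 0L),
    logloss = logloss,
    features = vapply(iters, function(it)
      paste(it$feature_set, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  hp <- do.call(rbind, lapply(iters, `[[`, "best_point"))
  traj <- cbind(traj, as.data.frame(hp))
  structure(list(trajectory = traj, iterations = iters,
                 selected_features = selected$feature_set,
                 selected_point = selected$best_point,
                 selected_logloss = selected$logloss,
                 evaluation = evaluation),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", nrow(x$trajectory), " iterations; selected ",
      length(x$selected_features), " feature(s), CV log-loss ",
      sprintf("%.4f", x$selected_logloss), "\n", sep = "")
  cat("  features:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the final booster on all samples at the selected point
#'
#' @param features Samples x features matrix.
#' @param labels 0/1 labels.
#' @param result A `selection_result` (or a list with `selected_features`
#'   and `selected_point`).
#' @return An `xgb.Booster` trained on the selected feature subset.
#' @export
fit_selected_model <- function(features, labels, result) {
  fit_booster(features[, result$selected_features, drop = FALSE],
              labels, result$selected_point)
}
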