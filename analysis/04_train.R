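#!/usr/bin/env Rscript

# Stage 4 — classifier training with embedded feature selection.
#
# Runs the recursive feature-elimination loop over the feature matrix: at
# each iteration, GP-UCB Bayesian optimization tunes the boosted-tree
# hyperparameters under 10-fold stratified cross-validated log-loss
# (probing all previous optima), fold-averaged gain importances are
# computed at the optimum, and the minimum-importance features are
# removed. The (feature set, hyperparameter) pair with the global minimum
# log-loss is evaluated and written under results/model/.

suppressMessages(library(hspmark))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

fx <- read_intensity_table("results/features/feature_matrix.tsv")
ann <- read_annotation("results/cohort/annotation.tsv")
stopifnot(identical(ann$sample_id, rownames(fx)))

cfg <- search_config(n1 = 4, n2 = 6, K = 10, seed = seed,
                     bounds = default_search_bounds(nrounds_max = 60))
res <- run_selection_loop(fx, ann$class, cfg)

dir.create("results/model", recursive = TRUE, showWarnings = FALSE)
write_tsv_report(res$trajectory, "results/model/trajectory.tsv")
ev <- res$evaluation
write_tsv_report(data.frame(
  metric = c("tp", "fp", "tn", "fn", "precision", "accuracy",
             "balanced_accuracy", "cv_logloss"),
  value = c(ev$confusion, ev$pooled$precision, ev$pooled$accuracy,
            ev$pooled$balanced_accuracy, res$selected_logloss)),
  "results/model/evaluation.tsv")
model <- fit_selected_model(fx, ann$class, res)
invisible(xgboost::xgb.save(model, "results/model/model.ubj"))

print(res)
print(ev)
cat(sprintf("trajectory: %d iterations, %d -> %d features\n",
            nrow(res$trajectory), res$trajectory$n_features[1],
            length(res$selected_features)))
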