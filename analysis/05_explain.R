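#!/usr/bin/env Rscript

# Stage 5 — model explanation and descriptive reports.
#
# Computes exact tree Shapley attributions of the selected model (default
# orientation: the non-cancer margin, so negative values push toward
# cancer), aggregates HSP70 and DNAJ family members, writes the
# attribution tables and the clipped z-score heatmap matrix under
# results/explain/.

suppressMessages(library(hspmark))

fx <- read_intensity_table("results/features/feature_matrix.tsv")
ann <- read_annotation("results/cohort/annotation.tsv")
model <- xgboost::xgb.load("results/model/model.ubj")
traj <- utils::read.delim("results/model/trajectory.tsv")
selected <- strsplit(
  traj$features[which.min(traj$logloss)], ";", fixed = TRUE)[[1]]

at <- shapley_attributions(model, fx[, selected, drop = FALSE])
fam <- list(
  HSP70 = intersect(c("HSPA2", "HSPA6", "HSPA8", "HSPA12", "HSPA5"),
                    selected),
  DNAJ = intersect(c("DNAJA1", "DNAJA2", "DNAJC11", "DNAJB1", "DNAJC5",
                     "DNAJC13"), selected))
agg <- aggregate_families(at, fam[lengths(fam) > 0])

dir.create("results/explain", recursive = TRUE, showWarnings = FALSE)
write_tsv_report(data.frame(sample_id = rownames(fx), group = ann$group,
                            as.data.frame(agg$values), check.names = FALSE),
                 "results/explain/attributions.tsv")
summ <- shap_summary(agg)
write_tsv_report(summ, "results/explain/shap_summary.tsv")

mat <- filter_low_detection(select_panel(
  read_intensity_table("results/cohort/intensities.tsv")))
hm <- zscore_clipped(mat)
write_tsv_report(data.frame(sample_id = rownames(mat), group = ann$group,
                            as.data.frame(hm$z_values), check.names = FALSE),
                 "results/explain/heatmap_z.tsv")

cat(sprintf("Shapley efficiency max residual: %.2e\n",
            max(abs(at$base_value + rowSums(at$values) - at$margin))))
cat("top features by mean |SHAP| (non-cancer margin):\n")
print(head(summ, 8), row.names = FALSE, digits = 3)
print(hm)
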