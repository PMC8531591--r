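#!/usr/bin/env Rscript

# Stage 3 — chaperone-network feature construction.
#
# Evaluates the default feature set over the filtered panel: every raw
# protein level plus the engineered chaperone relationships (HSP90
# homolog ratios, cochaperone-to-chaperone ratios, chaperonin couplings,
# stress-pair products, and the HSP70-family-to-DNAJ balance). Writes the
# feature matrix under results/features/.

suppressMessages(library(hspmark))

mat <- filter_low_detection(select_panel(
  read_intensity_table("results/cohort/intensities.tsv")))

panel <- default_panel()
kept <- panel_definition(colnames(mat),
                         lapply(panel$families, intersect, colnames(mat)))
feats <- default_feature_set(kept)
fx <- evaluate_feature_set(mat, feats)

dir.create("results/features", recursive = TRUE, showWarnings = FALSE)
write_intensity_table(fx, "results/features/feature_matrix.tsv")

kinds <- table(vapply(feats, `[[`, "", "kind"))
cat(sprintf("evaluated %d features over %d samples\n", ncol(fx), nrow(fx)))
print(kinds)
eng <- vapply(feats, `[[`, "", "name")
cat("engineered features:\n")
cat(paste(" ", eng[!eng %in% colnames(mat)], collapse = "\n"), "\n")
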