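#!/usr/bin/env Rscript

# Stage 2 — nonparametric differential-abundance screen.
#
# Reads the simulated cohort, selects the HSP panel, applies the >30%
# missingness filter, then screens every protein: Kruskal-Wallis across
# CTL plus the six cancer groups, Dunn's test of each cancer group against
# CTL, Holm-Bonferroni adjustment within each protein's six contrasts.
# Writes the long and wide screening tables under results/screen/.

suppressMessages(library(hspmark))

mat <- read_intensity_table("results/cohort/intensities.tsv")
ann <- read_annotation("results/cohort/annotation.tsv")

dir.create("results/screen", recursive = TRUE, showWarnings = FALSE)
mat <- select_panel(mat)
mat <- filter_low_detection(mat)
write_tsv_report(attr(mat, "filter_report"), "results/screen/filter_report.tsv")
cat(sprintf("detection filter kept %d of %d proteins\n", ncol(mat),
            nrow(attr(mat, "filter_report"))))

st <- screen_panel(mat, ann$group, alpha = 0.05)
write_tsv_report(as.data.frame(st), "results/screen/screening_long.tsv")
write_tsv_report(screening_wide(st), "results/screen/screening_wide.tsv")

sig <- st[st$significant, c("protein", "contrast", "dunn_z", "p_adj")]
sig <- sig[order(sig$p_adj), ]
cat(sprintf("significant (protein x cancer) cells at alpha 0.05: %d\n",
            nrow(sig)))
print(sig, row.names = FALSE, digits = 3)
up <- unique(sig$protein[sig$dunn_z > 0])
dn <- unique(sig$protein[sig$dunn_z < 0])
cat("up in cancer:", paste(up, collapse = ", "), "\n")
cat("down in cancer:", paste(dn, collapse = ", "), "\n")
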