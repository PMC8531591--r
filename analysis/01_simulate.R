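#!/usr/bin/env Rscript

# Stage 1 — simulate the urine-proteome cohort.
#
# Generates the default synthetic cohort: 231 donors across nine groups
# (six cancer types, two benign lung diseases, healthy controls), 25 HSP /
# cochaperone proteins on the iFOT display scale, 10% sentinel-coded
# missingness, and 1.0 log-unit differential shifts in the planted
# (protein, cancer group) cells. Writes the intensity table and annotation
# under results/cohort/.

suppressMessages(library(hspmark))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
cfg <- default_cohort_config(seed = seed)
co <- generate_cohort(cfg)
write_cohort(co, "results/cohort/intensities.tsv",
             "results/cohort/annotation.tsv")

print(co)
cat("groups:\n")
print(table(co$groups))
cat(sprintf("sentinel-coded entries: %.1f%%\n",
            100 * mean(co$matrix == cfg$sentinel)))
cat(sprintf("planted differential cells: %d\n", sum(cfg$effects != 0)))
cat("wrote results/cohort/intensities.tsv and annotation.tsv\n")
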