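#!/usr/bin/env Rscript
# Stage 1 — generate the three seeded synthetic cohorts: a 2x10-animal
# preclinical plasma table (126 metabolites, 11 planted lipid effects, two
# run-day blocks with QC samples), a 43-metabolite null urine table with
# per-sample dilution, and the ground-truth labels for both.

suppressPackageStartupMessages(library(metabotrans))
seed <- 2026L
dir.create("results", showWarnings = FALSE)

set.seed(seed)
cvn <- runif(126, 0.10, 0.15)  # per-metabolite CV at the study's design range
plasma <- simulate_preclinical(
  cohort_spec(cv_noise = cvn, block_drift = c(1, 1.25), seed = seed))
write_feature_table(plasma$table, "results/plasma_raw.csv")
write.csv(plasma$truth$classes, "results/plasma_truth_classes.csv",
          row.names = FALSE)
write.csv(plasma$truth$effects, "results/plasma_truth_effects.csv",
          row.names = FALSE)
cat(sprintf("plasma: %d samples x %d metabolites, %d planted effects, 2 blocks (drift 1.00/1.25)\n",
            nrow(plasma$table$abundance), ncol(plasma$table$abundance),
            sum(plasma$truth$effects$true_effect != 1)))

urine <- simulate_urine_null(urine_spec(seed = seed))
write_feature_table(urine$table, "results/urine_raw.csv")
write.csv(urine$truth$dilution, "results/urine_truth_dilution.csv",
          row.names = FALSE)
cat(sprintf("urine: %d samples x %d metabolites, no class signal, dilution CV %.2f\n",
            nrow(urine$table$abundance), ncol(urine$table$abundance), 0.35))
cat("wrote results/plasma_raw.csv, results/urine_raw.csv and truth tables\n")
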