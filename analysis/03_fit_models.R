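#!/usr/bin/env Rscript
# Stage 3 — chemometric modelling of both cohorts: exploratory NIPALS PCA,
# OPLS-DA with 1 predictive + 1 orthogonal component, 7-fold cross-validated
# Q2Y, 99-round permutation diagnostics, VIP scores, and the accept/reject
# verdict for each branch.

suppressPackageStartupMessages(library(metabotrans))
seed <- 2026L

diagnose <- function(table, label) {
  X <- ft_study_matrix(table)
  y <- ft_study_groups(table)
  pca <- nipals_pca(X, 2, scale. = TRUE)
  fit <- fit_oplsda(X, y)
  pt <- permutation_test(X, y, n_perm = 99, seed = seed)
  q <- model_quality(pt$q2_obs, pt$p_q2)
  cat(sprintf(
    "%s: PCA R2X(2) = %.3f | OPLS-DA R2X = %.3f, R2Y = %.3f, Q2Y = %.3f, pQ2 = %.2f -> %s%s\n",
    label, sum(pca$r2x), fit$diagnostics$r2x_cum, fit$diagnostics$r2y_cum,
    pt$q2_obs, pt$p_q2, q$verdict, if (q$rejected) " (rejected)" else ""))
  list(fit = fit, perm = pt, quality = q)
}

plasma <- read_feature_table("results/plasma_normalized.csv")
pl <- diagnose(plasma, "plasma")
write_latent_model(pl$fit, "results/plasma_oplsda_model.json")
vips <- vip(pl$fit)
write.csv(data.frame(metabolite = names(vips), vip = unname(vips)),
          "results/plasma_vip.csv", row.names = FALSE)
scores <- data.frame(sample_id = rownames(ft_study_matrix(plasma)),
                     t_pred = pl$fit$t[, 1], t_ortho = pl$fit$t_o[, 1])
write.csv(scores, "results/plasma_scores.csv", row.names = FALSE)

urine <- read_feature_table("results/urine_normalized.csv")
ur <- diagnose(urine, "urine")

jsonlite::write_json(list(
  plasma = c(pl$fit$diagnostics,
             list(q2y = pl$perm$q2_obs, p_q2 = pl$perm$p_q2,
                  rmsee = pl$fit$rmsee, verdict = pl$quality$verdict,
                  rejected = pl$quality$rejected)),
  urine = c(ur$fit$diagnostics,
            list(q2y = ur$perm$q2_obs, p_q2 = ur$perm$p_q2,
                 rmsee = ur$fit$rmsee, verdict = ur$quality$verdict,
                 rejected = ur$quality$rejected))
), "results/model_diagnostics.json", auto_unbox = TRUE, digits = NA)
cat("wrote model, VIP table, scores and diagnostics under results/\n")
if (ur$quality$rejected)
  cat("urine branch rejected: not carried forward to the human cohort\n")
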