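---
title: "Translational metabotyping of LPL-mediated HTG risk: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translational metabotyping of LPL-mediated HTG risk: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabotrans)
```

This vignette is the package's account of its statistical machinery: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic generators do and do not emulate, and
the numerical and design choices made where more than one reasonable option
existed.

## The scientific problem

Lipoprotein lipase (LPL) clears triglycerides from circulating lipoproteins;
even mild LPL underperformance shifts the plasma lipidome — specific
phosphatidylcholines, diacylglycerols, cholesterol esters and a
lysophosphatidylcholine rise before fasting triglycerides (TG) cross the
1.7 mmol/L clinical guideline boundary. The workflow trains a discriminant
model on a preclinical experiment where LPL is chemically inhibited (two
groups of 10 animals, 126 plasma metabolites measured as internal-standard
response ratios), validates it, compresses it to a metabolite signature, and
asks whether projecting the model onto nominally healthy humans isolates a
subgroup with an adverse lipid profile that the TG guideline alone misses.

## Preprocessing

**QC block correction** (`qc_block_normalize`). Mass-spectrometry batches
acquired over several run days drift multiplicatively. With pooled-QC samples
interleaved in every block, each value of metabolite *j* in block *b* is
multiplied by (global QC mean)ⱼ / (block-b QC mean)ⱼ, which equalizes QC
means across blocks exactly. One caveat is inherent to any QC anchoring: the
drift is only identifiable up to one global factor per metabolite, so the
corrected table equals the pre-drift table exactly only when the drift
factors average to one over the QC samples; otherwise it differs by that
single global factor, which is irrelevant to every downstream statistic used
here (all are scale-free per metabolite or refit scaling). Metabolites whose
QC mean is non-positive in some block cannot be anchored and are dropped into
the normalization report rather than silently imputed.

**Probabilistic quotient normalization** (`pqn_normalize`). Urine
concentration varies per sample; each sample is divided by the median of its
feature-wise ratios to a reference spectrum (default: the median spectrum of
the study samples), computed over features positive in both. Dilution is
likewise identifiable only up to a global scale. A sample sharing fewer than
three positive features with the reference is an error, not a guess.

**Z-scoring** (`zscore_columns`) uses the n−1 sample SD and is exposed as an
explicit optional stage; the discriminant model applies its own unit-variance
scaling internally, so z-scoring is *not* silently applied before it.

## Univariate screen

Each metabolite is tested with the Mann–Whitney U statistic (pair counting
with ½ credit for ties). With both groups small (n₁ + n₂ ≤ 12) and no ties
the two-sided p-value is exact from the null permutation distribution;
otherwise the normal approximation with tie and continuity corrections is
used — at 10 vs 10 the approximation is accurate and robust to the ties that
response-ratio data produce. P-values are floored at the smallest positive
double, never reported as zero. Benjamini–Hochberg adjustment is the standard
step-up procedure (delegated to `stats::p.adjust` behind a validating
wrapper). Fold change is the ratio of group means, case over control. Volcano
selection is deliberately two-sided (FC ≥ 2 **or** ≤ 0.5, q < 0.1): risk
signatures can include down-regulated metabolites (e.g. 3-hydroxybutyric
acid), so only-upward selection would be wrong even though thresholds are
usually quoted for the upper side.

The clinical indices use the standard fasting-state definitions with glucose
assayed in mg/dL (divided by 18 to mmol/L) and insulin in µg/L as measured:
HOMA-IR = (glucose/18)·insulin/22.5, HOMA-β = 20·insulin/(glucose/18 − 3.5)
(undefined at glucose ≤ 63 mg/dL, returned as missing), and
R-QUICKI = 1/(log₁₀ glucose + log₁₀ insulin + log₁₀ NEFA). This unit
convention reproduces reference control-group values for HOMA-IR exactly and
HOMA-β to rounding; R-QUICKI as defined yields ≈ 0.55 where reference tables
print 0.59 — published R-QUICKI unit conventions vary and no constant tuning
is attempted, the mismatch is simply documented here.

## The chemometrics core

`nipals_pca` computes components by the classical NIPALS/power iteration with
deflation. Initialization is deterministic (column of maximal variance);
convergence is a relative score change below 1e-10 with a 10,000-iteration
cap — power iteration converges slowly when the two leading eigenvalues are
close, and on the small matrices used here a generous cap costs microseconds
and buys eigendecomposition-grade accuracy. Every weight/loading vector is
signed so its largest-magnitude entry is positive, removing the sign
indeterminacy from stored artifacts.

`fit_oplsda` codes the class 0/1 (the midpoint 0.5 is the decision
threshold), scales X to unit variance, removes `n_ortho` class-orthogonal
components by the orthogonal projection construction (w_ortho ∝ p − (w'p)w,
then deflation by t_o p_o'), and fits `n_pred` predictive PLS1 components on
the filtered matrix. The default structure is 1 predictive + 1 orthogonal
component — standard practice for a two-class OPLS-DA. Everything collapses
into one linear form (coefficients b on the scaled scale, plus a raw-scale
form), so a serialized model predicts identically anywhere; with
`n_ortho = 0` the fit is exactly PLS1-DA, which the tests verify against an
independent Krylov-subspace oracle. RMSEE uses the n − 1 − n_pred
denominator. R2X is reported separately for predictive and orthogonal parts
plus their sum, since conventions differ on whether orthogonal variance
counts as "explained".

**Cross-validation** (`cross_validate_q2`): Q2Y = 1 − PRESS/SS over 7
stratified folds, scaling and the whole model refit inside every training
split; the fold count is capped at the smaller class size. **Permutation
diagnostics** (`permutation_test`): labels permuted uniformly, full refit and
cross-validation per permutation, add-one estimator
pQ2 = (1 + #{Q2ₚₑᵣₘ ≥ Q2ₒᵦₛ})/(n_perm + 1) so p-values are never zero. The
package default is 999 permutations; the Monte-Carlo suites in the tests and
the acceptance script use 49 per seed, the smallest count whose minimal pQ2
(0.02) still clears the 0.05 rejection rule, so that 100-seed recovery
studies stay fast. **Verdict** (`model_quality`): Q2Y < 0 none, ≤ 0.5 some,
> 0.5 good; rejected when Q2Y < 0 or pQ2 ≥ 0.05 — the rule that discards an
overfitted branch (the urine arm in the packaged workflow).

**VIP** is computed over predictive components only: orthogonal variation is
class-orthogonal by construction, and including it would reward features for
exactly the variation the model removed. This is a deliberate choice among
published VIP variants; mean squared VIP = 1 is enforced to 1e-8.

## Signature selection and translation

`select_signature` intersects q < 0.05 (strict) with VIP > 1 (strict) and
orders by VIP descending — boundary values are excluded on a literal reading
of both criteria. `project_cohort` then transfers the model across cohorts.
Two design choices here are the largest interpretive commitments of the
package:

- **Refit on matched features, not coefficient subsetting.** Dropping
  features from a fitted linear form invalidates the remaining coefficients;
  refitting on the feature intersection preserves the training signal on the
  usable panel. A minimum coverage of 0.8 (configurable) guards against
  projecting through a sparse match.
- **Within-cohort standardization of the target.** Rat and human abundances
  differ by platform, species and units, so the target cohort is z-scored
  with its own means and SDs rather than the training scaler. Both the
  full-feature and signature-only projection modes are implemented;
  full-feature is the default.

Guideline evaluation uses a single cut at 1.7 mmol/L for binary risk (a TG of
exactly 1.7 is at-risk, so the categories partition all values) and category
boundaries 1.7 / 2.3 / 5.6 mmol/L; published guideline texts quote both
5.6 mmol/L as the upper end of "high" and ≥ 5.7 mmol/L for "severe", leaving
a gap — this implementation uses the single 5.6 cut. The confusion matrix
takes the guideline as reference and the model as prediction, positive
condition = at-risk. `subgroup_compare` restricts to guideline-normal
subjects, splits them by model class, and screens clinical variables and
metabolites between the subgroups (Mann–Whitney + BH, volcano on the
metabolites).

## The synthetic generators

The generators define the study conditions for every test:

- **Preclinical** (`cohort_spec`, `simulate_preclinical`): 2 × 10 animals,
  126 metabolites (11 signature lipids, 21 amino acids and small molecules,
  94 filler lipid species across TG/DG/PC/LPC/ChoE/SM classes). Abundances
  are log-normal — response ratios are positive and their reported SEM/mean
  ratios (~3–8% at n = 10) are scale-proportional — with per-metabolite CV
  drawn 0.10–0.20 by default (the recovery suites use the 0.10–0.15 design
  range). Group effects are multiplicative, defaulting to the 11 published
  signature fold changes (1.17–1.51). Within each lipid class an
  equicorrelated shared Gaussian factor (ρ = 0.3) mimics co-regulation,
  which matters because OPLS-DA behavior depends on collinearity. Two
  run-day blocks with two pooled-QC injections each; drift multiplies block
  and QC samples identically.
- **Urine** (`urine_spec`, `simulate_urine_null`): 43 metabolites, no class
  signal, per-sample log-normal dilution (CV 0.35) recorded in the truth
  table so PQN can be validated against it.
- **Human** (`human_cohort_spec`, `simulate_human_cohort`): 140 subjects, a
  latent at-risk class at prevalence 0.5, multiplicative signature effect
  1.4 on the signature metabolites, healthy TG ~ N(1.1, 0.45) mmol/L floored
  at 0.3 so both guideline classes occur around the 1.7 threshold, and
  additive at-risk couplings TG +0.5, TC +0.5, LDL +0.4 mmol/L, ApoB
  +0.12 g/L with the remaining clinical panel (glucose, insulin, NEFA, LPL
  activity, age, BMI, sex) drawn uncoupled.

One master seed drives deterministic per-stream child seeds, so identical
spec + seed reproduces byte-identical cohorts and each stage is reproducible
in isolation.

What the generators do **not** emulate: spectral artifacts and peak-picking
errors, realistic inter-metabolite biochemical networks (only within-class
equicorrelation), heavy-tailed or missing-not-at-random abundance patterns,
and the very large (≥ 2-fold) fold changes reported in real human discordant
subgroups — the synthetic signature effect of 1.4 produces clear multivariate
separation but few volcano-threshold hits. Passing tests therefore
demonstrate that the algorithms recover known structure under the stated
noise model, not that any particular real cohort will behave identically.

## Problem sizes and numerical choices

The test suite and acceptance script run the recovery studies at the design
scale (10 vs 10 × 126 features; 140-subject human cohorts) with 100 seeds for
preclinical/urine recovery, 50 per effect size for translation, and 49
permutations per seed; these sizes give stable pass/fail margins for the
properties asserted. Degenerate inputs error eagerly and by name: constant
features before scaling, blocks without QC, samples sharing too few features
with the PQN reference, single-class fits, folds that lose a class. Ties in
the Mann–Whitney statistic get the tie-corrected normal approximation;
NIPALS sign indeterminacy is fixed by the largest-entry-positive convention;
p-values and permutation p-values are never zero by construction.

## Known limitations

- Two-class problems only; no multi-class OPLS-DA, O2PLS or kernel variants,
  and no automatic component-number selection.
- The cross-cohort projection assumes the rank ordering of feature
  importance transfers across species; within-cohort standardization removes
  scale but not distributional shape differences.
- QC anchoring corrects proportional drift only — no regression- or
  ComBat-style batch models.
- The subgroup screen at ~100 guideline-normal subjects has moderate power
  for clinical shifts of ~0.5 SD; aggregate behavior across seeds is the
  reliable signal, single cohorts will miss individual variables.
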