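#' @keywords internal
#' Deterministic child seed for a named random stream.
#' Keeps every derived seed a valid 32-bit integer.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629 + 1)
}

#' Plasma lipid signature of impaired LPL activity
#'
#' The eleven lipid species (phosphatidylcholines, a lysophosphatidylcholine,
#' diacylglycerols, a triacylglycerol and cholesterol esters) that separate
#' LPL-inhibited from control animals, with their control-group mean response
#' ratios and case/control fold changes. Used as the default planted effects
#' of the preclinical generator.
#'
#' @return data.frame with columns `metabolite`, `class`, `control_mean`,
#'   `fold_change`.
#' @export
signature_lipid_panel <- function() {
  data.frame(
    metabolite = c("PC 38:4", "LPC 18:0", "PC 36:4", "DG 36:4", "DG 34:3",
                   "DG 34:2", "TG 46:0", "ChoE (17:0)", "ChoE (18:0)",
                   "ChoE (16:0)", "ChoE (18:1)"),
    class = c("PC", "LPC", "PC", "DG", "DG", "DG", "TG",
              "ChoE", "ChoE", "ChoE", "ChoE"),
    control_mean = c(14.02, 50.40, 13.76, 1.53, 0.20, 0.85, 0.84,
                     0.13, 0.12, 2.02, 2.39),
    fold_change = c(1.46, 1.17, 1.29, 1.33, 1.50, 1.24, 1.37,
                    1.28, 1.51, 1.18, 1.41),
    stringsAsFactors = FALSE
  )
}

# Build the 126-metabolite plasma panel: 11 signature lipids plus null
# amino acids and filler lipid species across the same classes.
plasma_feature_panel <- function(n_features = 126) {
  sig <- signature_lipid_panel()
  aa <- c("Alanine", "Proline", "Valine", "Leucine", "Isoleucine", "Glycine",
          "Serine", "Threonine", "Methionine", "Phenylalanine", "Tyrosine",
          "Tryptophan", "Lysine", "Histidine", "Glutamine", "Glutamate",
          "Aspartate", "Arginine", "Asparagine", "Creatinine",
          "3-hydroxybutyric acid")
  filler_classes <- c("TG", "DG", "PC", "LPC", "ChoE", "SM")
  carbons <- list(TG = seq(44, 58, 2), DG = seq(30, 40, 2), PC = seq(30, 40, 2),
                  LPC = seq(14, 22, 2), ChoE = seq(14, 22, 2), SM = seq(30, 42, 2))
  filler <- character(0)
  filler_class <- character(0)
  for (cl in filler_classes) {
    for (cb in carbons[[cl]]) {
      for (db in 0:6) {
        nm <- if (cl == "ChoE") sprintf("ChoE (%d:%d)", cb, db)
              else sprintf("%s %d:%d", cl, cb, db)
        if (!(nm %in% sig$metabolite) && !(nm %in% filler)) {
          filler <- c(filler, nm)
          filler_class <- c(filler_class, cl)
        }
      }
    }
  }
  n_fill <- n_features - nrow(sig) - length(aa)
  if (n_fill < 0) stop("n_features too small for the plasma panel")
  keep <- seq_len(n_fill)
  data.frame(
    metabolite = c(sig$metabolite, aa, filler[keep]),
    class = c(sig$class, rep("amino-acid", length(aa)), filler_class[keep]),
    stringsAsFactors = FALSE
  )
}

#' Specification of a two-group preclinical cohort simulation
#'
#' Describes the data-generating process for a control vs LPL-inhibited
#' plasma metabolomics experiment: log-normal abundances per metabolite,
#' multiplicative group effects, equicorrelated noise within each lipid
#' class via one shared Gaussian factor, and optional multiplicative
#' run-day drift with interleaved QC (pooled) samples.
#'
#' @param n_per_group animals per group (default 10).
#' @param features data.frame with columns `metabolite`, `class`; defaults
#'   to the 126-metabolite plasma panel.
#' @param effect_map named numeric vector of multiplicative group effects
#'   (case mean / control mean); unnamed metabolites default to 1. Defaults
#'   to the eleven signature lipid fold changes.
#' @param base_means named numeric vector of control-group means; metabolites
#'   not named get reproducible pseudo-random means spanning the panel's
#'   typical response-ratio range.
#' @param cv_noise per-metabolite coefficient of variation; scalar or named
#'   vector. Default draws each CV uniformly in \[0.10, 0.20\].
#' @param within_class_corr equicorrelation in \[0, 1) among features of one
#'   lipid class (default 0.3).
#' @param n_blocks run-day block count (default 2).
#' @param block_drift per-block multiplicative drift factors (default all 1;
#'   length `n_blocks`).
#' @param qc_per_block pooled-QC injections per block (default 2).
#' @param seed integer master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10,
                        features = plasma_feature_panel(),
                        effect_map = NULL,
                        base_means = NULL,
                        cv_noise = NULL,
                        within_class_corr = 0.3,
                        n_blocks = 2,
                        block_drift = rep(1, n_blocks),
                        qc_per_block = 2,
                        seed = 1L) {
  stopifnot(is.data.frame(features), all(c("metabolite", "class") %in% names(features)))
  p <- nrow(features)
  if (is.null(effect_map)) {
    sig <- signature_lipid_panel()
    effect_map <- stats::setNames(sig$fold_change, sig$metabolite)
    effect_map <- effect_map[names(effect_map) %in% features$metabolite]
  }
  bad <- setdiff(names(effect_map), features$metabolite)
  if (length(bad)) stop("effect_map names absent from panel: ", paste(bad, collapse = ", "))
  if (any(effect_map <= 0))
    stop("non-positive effect for metabolite: ",
         paste(names(effect_map)[effect_map <= 0], collapse = ", "))
  effects <- stats::setNames(rep(1, p), features$metabolite)
  effects[names(effect_map)] <- effect_map

  means <- stats::setNames(rep(NA_real_, p), features$metabolite)
  if (!is.null(base_means)) means[names(base_means)] <- base_means
  sig <- signature_lipid_panel()
  hit <- intersect(sig$metabolite, names(means)[is.na(means)])
  means[hit] <- sig$control_mean[match(hit, sig$metabolite)]
  if (any(is.na(means))) {
    set.seed(child_seed(seed, "base_means"))
    means[is.na(means)] <- exp(stats::runif(sum(is.na(means)), log(0.1), log(60)))
  }

  if (is.null(cv_noise)) {
    set.seed(child_seed(seed, "cv"))
    cv_noise <- stats::runif(p, 0.10, 0.20)
  }
  cv <- if (length(cv_noise) == 1) stats::setNames(rep(cv_noise, p), features$metabolite)
        else {
          if (is.null(names(cv_noise))) stats::setNames(cv_noise, features$metabolite)
          else {
            full <- stats::setNames(rep(stats::median(cv_noise), p), features$metabolite)
            full[names(cv_noise)] <- cv_noise
            full
          }
        }
  if (any(cv <= 0))
    stop("non-positive CV for metabolite: ", paste(names(cv)[cv <= 0], collapse = ", "))
  if (within_class_corr < 0 || within_class_corr >= 1)
    stop("within_class_corr must be in [0, 1)")
  if (length(block_drift) != n_blocks) stop("block_drift must have length n_blocks")
  if (n_per_group < 3) stop("n_per_group must be at least 3")

  structure(list(
    n_per_group = n_per_group, features = features, effects = effects,
    base_means = means, cv = cv, within_class_corr = within_class_corr,
    n_blocks = n_blocks, block_drift = block_drift, qc_per_block = qc_per_block,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Draw a samples-x-features log-normal abundance matrix with equicorrelated
# within-class noise. effects_multiplier is a per-sample x per-feature matrix
# of multiplicative mean shifts (1 = none).
draw_lognormal <- function(n, spec, effect_mult, stream) {
  p <- nrow(spec$features)
  sdlog <- sqrt(log(1 + spec$cv^2))
  meanlog <- log(spec$base_means) - sdlog^2 / 2
  rho <- spec$within_class_corr
  cls <- spec$features$class
  set.seed(child_seed(spec$seed, stream))
  zcls <- matrix(stats::rnorm(n * length(unique(cls))), n,
                 dimnames = list(NULL, unique(cls)))
  eps <- matrix(stats::rnorm(n * p), n, p)
  zz <- sqrt(rho) * zcls[, cls, drop = FALSE] + sqrt(1 - rho) * eps
  logx <- matrix(meanlog, n, p, byrow = TRUE) + log(effect_mult) +
    sweep(zz, 2, sdlog, `*`)
  x <- exp(logx)
  colnames(x) <- spec$features$metabolite
  x
}

# Round-robin block assignment balanced across the sample sequence.
assign_blocks <- function(n, n_blocks) ((seq_len(n) - 1) %% n_blocks) + 1

#' Simulate a two-group preclinical plasma cohort
#'
#' Generates strictly positive log-normal abundances for `2 * n_per_group`
#' animals; case-group means equal control means times the spec's effect map.
#' Pooled QC samples are interleaved per run-day block and block drift is
#' applied multiplicatively to every sample in a block (QCs drift with the
#' study samples, so QC-based correction can undo it).
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `table` (a [feature_table()]) and `truth`
#'   (list: `classes` data.frame sample_id/class, `effects` data.frame
#'   metabolite/true_effect).
#' @export
simulate_preclinical <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- 2 * spec$n_per_group
  p <- nrow(spec$features)
  grp <- rep(c("CON", "CASE"), each = spec$n_per_group)
  eff <- matrix(1, n, p)
  eff[grp == "CASE", ] <- matrix(spec$effects, spec$n_per_group, p, byrow = TRUE)
  x <- draw_lognormal(n, spec, eff, "preclinical")
  sample_id <- sprintf("rat_%02d", seq_len(n))
  rownames(x) <- sample_id
  blocks <- assign_blocks(n, spec$n_blocks)

  # pooled QC: geometric mean profile of the study samples + analytical noise
  n_qc <- spec$n_blocks * spec$qc_per_block
  qc_profile <- exp(colMeans(log(x)))
  set.seed(child_seed(spec$seed, "qc"))
  qc <- exp(matrix(log(qc_profile), n_qc, p, byrow = TRUE) +
              matrix(stats::rnorm(n_qc * p, 0, 0.05), n_qc, p))
  qc_id <- sprintf("qc_%02d", seq_len(n_qc))
  rownames(qc) <- qc_id
  qc_blocks <- rep(seq_len(spec$n_blocks), each = spec$qc_per_block)

  ab <- rbind(x, qc)
  meta <- data.frame(
    sample_id = c(sample_id, qc_id),
    cohort = "preclinical",
    group = c(grp, rep("QC", n_qc)),
    block = c(blocks, qc_blocks),
    is_qc = c(rep(FALSE, n), rep(TRUE, n_qc)),
    stringsAsFactors = FALSE
  )
  tab <- feature_table(ab, meta)
  if (any(spec$block_drift != 1))
    tab <- inject_run_day_drift(tab, factors = spec$block_drift)
  list(
    table = tab,
    truth = list(
      classes = data.frame(sample_id = sample_id, class = grp,
                           stringsAsFactors = FALSE),
      effects = data.frame(metabolite = spec$features$metabolite,
                           true_effect = unname(spec$effects),
                           stringsAsFactors = FALSE)
    )
  )
}

#' Default specification of the null urine cohort
#'
#' 43 urinary metabolites with no group signal and per-sample dilution
#' variation, emulating an NMR urine screen whose discriminant model should
#' be rejected.
#'
#' @param n_per_group animals per group (default 10).
#' @param dilution_cv coefficient of variation of per-sample dilution
#'   factors (default 0.35).
#' @param seed integer master seed.
#' @return A `cohort_spec` with an extra `dilution_cv` field.
#' @export
urine_spec <- function(n_per_group = 10, dilution_cv = 0.35, seed = 1L) {
  mets <- c("TMAO", "Phenylacetylglycine", "2-Deoxycytidine", "Leucine",
            "Creatinine", "Citrate", "Hippurate", "Taurine", "Betaine",
            "Dimethylamine", "Dimethylglycine", "Succinate", "2-Oxoglutarate",
            "Fumarate", "Formate", "Acetate", "Lactate", "Alanine", "Glycine",
            "Valine", "Isoleucine", "Threonine", "Pyruvate", "Allantoin",
            "Urea", "Trigonelline", "N-Methylnicotinamide", "Indoxyl sulfate",
            "4-Hydroxyphenylacetate", "3-Indoxylsulfate glycoside", "Malonate",
            "Methylamine", "Sarcosine", "Choline", "Ethanolamine",
            "Glucose (urine)", "myo-Inositol", "Tartrate", "3-Hydroxybutyrate",
            "Acetoacetate", "Acetone", "Benzoate", "Nicotinate")
  features <- data.frame(metabolite = mets, class = "other",
                         stringsAsFactors = FALSE)
  sp <- cohort_spec(
    n_per_group = n_per_group, features = features,
    effect_map = stats::setNames(numeric(0), character(0)),
    within_class_corr = 0, n_blocks = 1, qc_per_block = 1, seed = seed
  )
  sp$dilution_cv <- dilution_cv
  sp
}

#' Simulate a null urine cohort with dilution variation
#'
#' Abundances carry no class signal (at most a handful of near-unity effects
#' are tolerated); each sample is multiplied by its own dilution factor,
#' recorded in the truth table so probabilistic quotient normalization can be
#' validated against it.
#'
#' @param spec a [urine_spec()] (any `cohort_spec` with `dilution_cv` works).
#' @return list with `table`, `truth` (classes, effects, `dilution` data.frame
#'   sample_id/factor).
#' @export
simulate_urine_null <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  non_null <- spec$effects[abs(spec$effects - 1) > 0.05]
  if (length(non_null) > 4)
    stop("urine generator expects a null effect map (> 4 non-unit effects found)")
  n <- 2 * spec$n_per_group
  p <- nrow(spec$features)
  grp <- rep(c("CON", "CASE"), each = spec$n_per_group)
  eff <- matrix(1, n, p)
  eff[grp == "CASE", ] <- matrix(spec$effects, spec$n_per_group, p, byrow = TRUE)
  x <- draw_lognormal(n, spec, eff, "urine")
  dil_cv <- if (is.null(spec$dilution_cv)) 0.35 else spec$dilution_cv
  set.seed(child_seed(spec$seed, "dilution"))
  sdlog <- sqrt(log(1 + dil_cv^2))
  dil <- exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  x <- x * dil
  sample_id <- sprintf("urine_%02d", seq_len(n))
  rownames(x) <- sample_id
  meta <- data.frame(
    sample_id = sample_id, cohort = "preclinical", group = grp,
    block = 1L, is_qc = FALSE, stringsAsFactors = FALSE
  )
  list(
    table = feature_table(x, meta),
    truth = list(
      classes = data.frame(sample_id = sample_id, class = grp,
                           stringsAsFactors = FALSE),
      effects = data.frame(metabolite = spec$features$metabolite,
                           true_effect = unname(spec$effects),
                           stringsAsFactors = FALSE),
      dilution = data.frame(sample_id = sample_id, factor = dil,
                            stringsAsFactors = FALSE)
    )
  )
}

#' Specification of a synthetic human validation cohort
#'
#' A cohort of nominally healthy volunteers with a latent at-risk class:
#' at-risk subjects carry a multiplicative shift on the signature metabolites
#' and additive mean shifts on clinical lipids (TG, TC, LDL in mmol/L, ApoB
#' in g/L). Healthy triglycerides centre at 1.1 mmol/L so both guideline
#' classes occur around the 1.7 mmol/L threshold.
#'
#' @param n_subjects cohort size (default 140).
#' @param prevalence_at_risk latent at-risk fraction in (0, 1) (default 0.5).
#' @param signature_effect multiplicative shift on signature metabolites in
#'   at-risk subjects (default 1.4).
#' @param clinical_coupling named numeric additive shifts for at-risk
#'   subjects; names among `tg`, `tc`, `ldl`, `apob`.
#' @param tg_guideline_threshold mmol/L (default 1.7).
#' @param seed integer master seed.
#' @return A list of class `human_cohort_spec`.
#' @export
human_cohort_spec <- function(n_subjects = 140,
                              prevalence_at_risk = 0.5,
                              signature_effect = 1.4,
                              clinical_coupling = c(tg = 0.5, tc = 0.5,
                                                    ldl = 0.4, apob = 0.12),
                              tg_guideline_threshold = 1.7,
                              seed = 1L) {
  if (prevalence_at_risk <= 0 || prevalence_at_risk >= 1)
    stop("prevalence_at_risk must be in (0, 1)")
  if (signature_effect <= 0) stop("signature_effect must be positive")
  coup <- c(tg = 0, tc = 0, ldl = 0, apob = 0)
  coup[names(clinical_coupling)] <- clinical_coupling
  structure(list(
    n_subjects = n_subjects, prevalence_at_risk = prevalence_at_risk,
    signature_effect = signature_effect, clinical_coupling = coup,
    tg_guideline_threshold = tg_guideline_threshold, seed = as.integer(seed)
  ), class = "human_cohort_spec")
}

#' Simulate a human validation cohort coupled to a metabolite signature
#'
#' Latent at-risk subjects (Bernoulli with the spec's prevalence) carry the
#' spec's multiplicative effect on every signature metabolite and additive
#' shifts on clinical TG/TC/LDL/ApoB; all clinical variables are present for
#' every subject and strictly positive.
#'
#' @param spec a [human_cohort_spec()].
#' @param signature character vector of signature metabolite names, or a
#'   `signature` object from [select_signature()].
#' @param features data.frame metabolite/class panel assayed in the cohort
#'   (default: the plasma panel).
#' @return list with `table` (feature_table), `clinical` (data.frame), and
#'   `truth` (classes data.frame with latent class labels).
#' @export
simulate_human_cohort <- function(spec, signature,
                                  features = plasma_feature_panel()) {
  stopifnot(inherits(spec, "human_cohort_spec"))
  sig_names <- if (inherits(signature, "signature")) signature$metabolite
               else as.character(signature)
  if (!length(sig_names)) stop("signature must be non-empty")
  missing_sig <- setdiff(sig_names, features$metabolite)
  if (length(missing_sig))
    stop("signature metabolites absent from the cohort panel: ",
         paste(missing_sig, collapse = ", "))

  n <- spec$n_subjects
  set.seed(child_seed(spec$seed, "latent_class"))
  at_risk <- stats::rbinom(n, 1, spec$prevalence_at_risk) == 1

  base <- cohort_spec(n_per_group = max(3, ceiling(n / 2)), features = features,
                      effect_map = stats::setNames(numeric(0), character(0)),
                      within_class_corr = 0.3, n_blocks = 1, seed = spec$seed)
  p <- nrow(features)
  eff <- matrix(1, n, p, dimnames = list(NULL, features$metabolite))
  eff[at_risk, sig_names] <- spec$signature_effect
  base$seed <- spec$seed
  x <- draw_lognormal(n, base, eff, "human_metabolome")
  sample_id <- sprintf("subj_%03d", seq_len(n))
  rownames(x) <- sample_id
  meta <- data.frame(
    sample_id = sample_id, cohort = "human", group = "volunteer",
    block = 1L, is_qc = FALSE, stringsAsFactors = FALSE
  )

  set.seed(child_seed(spec$seed, "clinical"))
  coup <- spec$clinical_coupling
  pos <- function(x, floor) pmax(x, floor)
  tg <- pos(stats::rnorm(n, 1.1, 0.45) + at_risk * coup[["tg"]], 0.3)
  tc <- pos(stats::rnorm(n, 4.9, 0.8) + at_risk * coup[["tc"]], 2.0)
  hdl <- pos(stats::rnorm(n, 1.4, 0.3) - at_risk * 0.05, 0.5)
  ldl <- pos(stats::rnorm(n, 3.0, 0.7) + at_risk * coup[["ldl"]], 1.0)
  apob <- pos(stats::rnorm(n, 0.95, 0.2) + at_risk * coup[["apob"]], 0.3)
  clinical <- data.frame(
    sample_id = sample_id,
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = round(stats::runif(n, 20, 65)),
    bmi = round(pos(stats::rnorm(n, 24.5, 3), 16), 1),
    tg_mmol_l = tg, tc_mmol_l = tc, hdl_mmol_l = hdl, ldl_mmol_l = ldl,
    apob_g_l = apob,
    glucose_mg_dl = pos(stats::rnorm(n, 90, 9), 50),
    insulin_ug_l = pos(stats::rnorm(n, 0.9, 0.3), 0.1),
    nefa_mmol_l = pos(stats::rnorm(n, 0.5, 0.12), 0.05),
    lpl_activity = pos(stats::rnorm(n, 5.2, 0.6), 1),
    stringsAsFactors = FALSE
  )
  list(
    table = feature_table(x, meta),
    clinical = clinical,
    truth = list(classes = data.frame(
      sample_id = sample_id,
      class = ifelse(at_risk, "at-risk", "healthy"),
      stringsAsFactors = FALSE
    ))
  )
}

#' Apply multiplicative run-day drift to a feature table
#'
#' Every value in block b is multiplied by that block's factor; QC samples
#' drift identically to study samples, which is what makes QC-anchored
#' correction able to undo the drift exactly.
#'
#' @param table a [feature_table()] whose meta assigns every sample a block.
#' @param factors numeric vector of per-block factors (length = number of
#'   blocks) or a blocks-x-metabolites matrix of per-metabolite factors.
#' @return The drifted `feature_table`.
#' @export
inject_run_day_drift <- function(table, factors) {
  stopifnot(inherits(table, "feature_table"))
  blocks <- table$meta$block
  ub <- sort(unique(blocks))
  for (b in ub) {
    if (!any(table$meta$is_qc[blocks == b]))
      stop("block ", b, " contains no QC sample")
  }
  fm <- if (is.matrix(factors)) {
    if (nrow(factors) != length(ub)) stop("factor matrix must have one row per block")
    factors
  } else {
    if (length(factors) != length(ub)) stop("need one drift factor per block")
    matrix(factors, length(ub), ncol(table$abundance))
  }
  if (any(fm <= 0)) stop("drift factors must be positive")
  ab <- table$abundance
  for (i in seq_along(ub)) {
    idx <- blocks == ub[i]
    ab[idx, ] <- sweep(ab[idx, , drop = FALSE], 2, fm[i, ], `*`)
  }
  feature_table(ab, table$meta)
}
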