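#' Select the predictive metabolite signature
#'
#' Intersects the univariate and multivariate criteria: a metabolite enters
#' the signature iff its BH-adjusted q is strictly below `q_max` and its VIP
#' strictly above `vip_min`. The result is ordered by VIP, descending. An
#' empty signature is a valid result, not an error.
#'
#' @param univ a `univariate_result` from [screen_features()].
#' @param vips named numeric VIP vector from [vip()].
#' @param q_max FDR ceiling (default 0.05, exclusive).
#' @param vip_min VIP floor (default 1, exclusive).
#' @return data.frame of class `signature` with columns `metabolite`, `vip`,
#'   `q`, `fc`; attributes `q_max`, `vip_min`.
#' @export
select_signature <- function(univ, vips, q_max = 0.05, vip_min = 1) {
  common <- intersect(univ$metabolite, names(vips))
  if (!length(common))
    stop("univariate results and VIP scores share no features")
  u <- univ[match(common, univ$metabolite), ]
  v <- vips[common]
  keep <- u$q < q_max & v > vip_min
  out <- data.frame(
    metabolite = common[keep], vip = unname(v[keep]),
    q = u$q[keep], fc = u$fc[keep], stringsAsFactors = FALSE
  )
  out <- out[order(-out$vip), ]
  rownames(out) <- NULL
  attr(out, "q_max") <- q_max
  attr(out, "vip_min") <- vip_min
  class(out) <- c("signature", "data.frame")
  out
}

#' Reconcile model features with a target cohort's feature panel
#'
#' Case-insensitive, whitespace-normalized exact name matching.
#'
#' @param model_features character vector of feature names the model needs.
#' @param cohort_features character vector of names available in the target.
#' @return list with `mapping` (named character: model name -> cohort name),
#'   `missing` (model features with no match) and `coverage` (matched
#'   fraction of model features).
#' @export
match_features <- function(model_features, cohort_features) {
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  idx <- match(norm(model_features), norm(cohort_features))
  matched <- !is.na(idx)
  list(
    mapping = stats::setNames(cohort_features[idx[matched]],
                              model_features[matched]),
    missing = model_features[!matched],
    coverage = mean(matched)
  )
}

#' Project a preclinically trained discriminant model onto a target cohort
#'
#' Refits the OPLS-DA model on the training cohort restricted to the
#' features present in the target panel (all matched features, or the
#' signature members only), then applies the resulting linear form to the
#' target cohort. The target matrix is standardized with its own means and
#' SDs — abundance scales differ across species and platforms, so the
#' training scaler is deliberately not transferred. Subjects score through
#' the coded-class midpoint: at-risk iff the continuous score >= 0.5.
#'
#' @param train_table training [feature_table()] (QC excluded).
#' @param target_table target [feature_table()].
#' @param mode `"full"` (all matched features, default) or
#'   `"signature-only"`.
#' @param signature required when `mode = "signature-only"`: a `signature`
#'   or character vector of metabolite names.
#' @param min_coverage minimal matched fraction of model features before
#'   projection is allowed (default 0.8).
#' @param n_pred,n_ortho component structure for the refit.
#' @param positive label coded 1 in training (default as [fit_oplsda()]).
#' @return list with `model` (the refit `opls_model`), `classification`
#'   (data.frame: sample_id, y_hat, model_class) and `match` (the
#'   [match_features()] report).
#' @export
project_cohort <- function(train_table, target_table,
                           mode = c("full", "signature-only"),
                           signature = NULL, min_coverage = 0.8,
                           n_pred = 1, n_ortho = 1, positive = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(train_table, "feature_table"),
            inherits(target_table, "feature_table"))
  train_x <- ft_study_matrix(train_table)
  train_y <- ft_study_groups(train_table)
  target_x <- ft_study_matrix(target_table)

  wanted <- if (mode == "signature-only") {
    if (is.null(signature)) stop("signature-only mode requires a signature")
    sig <- if (inherits(signature, "signature")) signature$metabolite
           else as.character(signature)
    if (!length(sig)) stop("signature is empty")
    intersect(colnames(train_x), sig)
  } else colnames(train_x)

  mf <- match_features(wanted, colnames(target_x))
  if (mf$coverage < min_coverage)
    stop(sprintf(
      "feature coverage %.2f below min_coverage %.2f; missing: %s",
      mf$coverage, min_coverage, paste(mf$missing, collapse = ", ")))
  feats <- names(mf$mapping)

  model <- fit_oplsda(train_x[, feats, drop = FALSE], train_y,
                      n_pred = n_pred, n_ortho = n_ortho, positive = positive)

  tx <- target_x[, unname(mf$mapping), drop = FALSE]
  colnames(tx) <- feats
  sds <- apply(tx, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance target feature(s): ",
         paste(feats[sds == 0], collapse = ", "))
  tz <- scale(tx)
  pr <- predict(model, tz, scaling = "none")
  list(
    model = model,
    classification = data.frame(
      sample_id = rownames(target_x),
      y_hat = pr$y_hat,
      model_class = ifelse(pr$class == model$scaling$positive,
                           "at-risk", "healthy"),
      stringsAsFactors = FALSE
    ),
    match = mf
  )
}

#' Classify triglycerides against clinical guideline thresholds
#'
#' Categories: normal < 1.7 <= borderline < 2.3 <= high < 5.6 <= severe
#' (mmol/L); binary risk is TG >= the normal/borderline boundary.
#'
#' @param tg_mmol_l fasting triglycerides, mmol/L, strictly positive.
#' @param tg_normal_max,tg_borderline_max,tg_high_max category boundaries in
#'   mmol/L (defaults 1.7, 2.3, 5.6; must be strictly increasing).
#' @return data.frame with columns `tg_mmol_l`, `category` (ordered factor)
#'   and `at_risk` (logical).
#' @export
guideline_classify <- function(tg_mmol_l, tg_normal_max = 1.7,
                               tg_borderline_max = 2.3, tg_high_max = 5.6) {
  if (any(!is.finite(tg_mmol_l)) || any(tg_mmol_l <= 0))
    stop("TG values must be positive")
  if (!(tg_normal_max < tg_borderline_max && tg_borderline_max < tg_high_max))
    stop("guideline thresholds must be strictly increasing")
  category <- cut(tg_mmol_l,
                  breaks = c(0, tg_normal_max, tg_borderline_max, tg_high_max, Inf),
                  labels = c("normal", "borderline", "high", "severe"),
                  right = FALSE, ordered_result = TRUE)
  data.frame(tg_mmol_l = tg_mmol_l, category = category,
             at_risk = tg_mmol_l >= tg_normal_max)
}

#' Confusion matrix of model vs guideline classification
#'
#' Positive condition = at-risk; the guideline label is the reference, the
#' model label the prediction.
#'
#' @param model_at_risk logical vector: model calls the subject at-risk.
#' @param guideline_at_risk logical vector, same length: guideline risk.
#' @return list of class `confusion_report` with `tp`, `fp`, `tn`, `fn`,
#'   `n`, `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_report <- function(model_at_risk, guideline_at_risk) {
  if (length(model_at_risk) != length(guideline_at_risk))
    stop("label vectors differ in length")
  model_at_risk <- as.logical(model_at_risk)
  guideline_at_risk <- as.logical(guideline_at_risk)
  if (anyNA(model_at_risk) || anyNA(guideline_at_risk))
    stop("labels must be binary with no missing values")
  tp <- sum(model_at_risk & guideline_at_risk)
  fp <- sum(model_at_risk & !guideline_at_risk)
  tn <- sum(!model_at_risk & !guideline_at_risk)
  fn <- sum(!model_at_risk & guideline_at_risk)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = tp + fp + tn + fn,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp)
  ), class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("<confusion_report> positive = at-risk\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d  (N = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n))
  cat(sprintf("  accuracy %.2f  sensitivity %.2f  specificity %.2f\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Metrics of a confusion matrix given as counts
#'
#' @param tp,fp,tn,fn cell counts (positive condition = at-risk).
#' @return A `confusion_report`.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  confusion_report(
    model_at_risk = rep(c(TRUE, TRUE, FALSE, FALSE), c(tp, fp, tn, fn)),
    guideline_at_risk = rep(c(TRUE, FALSE, FALSE, TRUE), c(tp, fp, tn, fn))
  )
}

#' Characterize the guideline-normal, model-at-risk subgroup
#'
#' Restricts to guideline-normal subjects, splits them by the model class,
#' and compares (a) clinical variables and (b) metabolite abundances between
#' the two subgroups with Mann-Whitney tests and BH correction; the
#' metabolite comparison additionally passes through [volcano_select()].
#'
#' @param classification data.frame from [project_cohort()]
#'   (`sample_id`, `model_class`).
#' @param clinical clinical data.frame with `sample_id` and `tg_mmol_l` plus
#'   numeric clinical columns.
#' @param features target [feature_table()].
#' @param tg_normal_max guideline normal/borderline boundary (default 1.7).
#' @param fc_min,fdr_max volcano thresholds (defaults 2 and 0.1).
#' @return list with `sizes` (named counts), `clinical_tests`,
#'   `metabolite_tests` (both `univariate_result`s or NULL), `volcano`.
#' @export
subgroup_compare <- function(classification, clinical, features,
                             tg_normal_max = 1.7, fc_min = 2, fdr_max = 0.1) {
  stopifnot(inherits(features, "feature_table"))
  merged <- merge(classification, clinical, by = "sample_id")
  normal <- merged[merged$tg_mmol_l < tg_normal_max, ]
  sizes <- c(
    guideline_normal = nrow(normal),
    concordant_healthy = sum(normal$model_class == "healthy"),
    discordant_at_risk = sum(normal$model_class == "at-risk")
  )
  if (min(sizes[-1]) < 3) {
    warning("a subgroup has fewer than 3 subjects; tests skipped")
    return(list(sizes = sizes, clinical_tests = NULL,
                metabolite_tests = NULL, volcano = NULL))
  }
  labels <- normal$model_class
  clin_vars <- setdiff(names(clinical),
                       c("sample_id", "sex"))
  clin_num <- normal[clin_vars]
  clin_num <- clin_num[vapply(clin_num, is.numeric, logical(1))]
  clinical_tests <- screen_features(as.matrix(clin_num), labels,
                                    case = "at-risk")
  fmat <- ft_study_matrix(features)[normal$sample_id, , drop = FALSE]
  metabolite_tests <- screen_features(fmat, labels, case = "at-risk")
  list(
    sizes = sizes,
    clinical_tests = clinical_tests,
    metabolite_tests = metabolite_tests,
    volcano = volcano_select(metabolite_tests, fc_min, fdr_max)
  )
}
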