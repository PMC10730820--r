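#' Mann-Whitney U test for two independent samples
#'
#' U counts the pairs with `x > y` plus half the tied pairs. For small
#' untied problems (n1 + n2 <= 12) the two-sided p-value is exact (null
#' permutation distribution of U); otherwise the normal approximation with
#' tie correction and continuity correction is used. p-values are floored at
#' the smallest positive double, never reported as zero.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `U` and `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 finite observations")
  n1 <- length(x); n2 <- length(y)
  cmp <- outer(x, y, `-`)
  U <- sum(cmp > 0) + 0.5 * sum(cmp == 0)
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && n1 + n2 <= 12) {
    # exact two-sided tail of the null U distribution
    mu <- n1 * n2 / 2
    lo <- min(U, n1 * n2 - U)
    p <- stats::pwilcox(lo, n1, n2) +
      (1 - stats::pwilcox(n1 * n2 - lo - 1, n1, n2))
    if (U == mu) p <- 1
  } else {
    r <- rank(c(x, y))
    nties <- table(r)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(nties^3 - nties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, p = max(min(p, 1), .Machine$double.xmin))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1, returned in the
#' original input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values (adjusted p controlling the FDR).
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Fold change of group means
#'
#' @param mean_case,mean_ctrl group means; the control mean must be positive.
#' @return `mean_case / mean_ctrl`.
#' @export
fold_change <- function(mean_case, mean_ctrl) {
  if (any(mean_ctrl <= 0)) stop("control mean must be positive")
  mean_case / mean_ctrl
}

#' Per-metabolite two-group screen
#'
#' For every metabolite: group means and SEMs, Mann-Whitney U and two-sided
#' p, Benjamini-Hochberg q, fold change (case over control), and selection
#' flags at p < 0.05 and q < 0.05. Metabolites with fewer than 2 finite
#' values in either group are dropped with a warning.
#'
#' @param table a [feature_table()] (QC samples are excluded) or numeric
#'   matrix.
#' @param labels group labels (ignored when `table` is a `feature_table`;
#'   taken from its metadata then). Exactly two groups required.
#' @param case which label is the case group; default the label that is not
#'   `"CON"` if present, otherwise the second level.
#' @return data.frame of class `univariate_result`, one row per metabolite,
#'   with attributes `n_raw_discoveries` and `n_fdr_discoveries`.
#' @export
screen_features <- function(table, labels = NULL, case = NULL) {
  if (inherits(table, "feature_table")) {
    m <- ft_study_matrix(table)
    labels <- ft_study_groups(table)
  } else {
    m <- as.matrix(table)
    if (is.null(labels)) stop("labels required for a plain matrix")
  }
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2) stop("exactly two groups required, got ", length(lv))
  if (is.null(case)) case <- if ("CON" %in% lv) setdiff(lv, "CON") else lv[2]
  ctrl <- setdiff(lv, case)
  if (min(table(labels)) < 3) stop("each group needs at least 3 samples")

  res <- lapply(colnames(m), function(met) {
    xs <- m[labels == case, met]; ys <- m[labels == ctrl, met]
    xs <- xs[is.finite(xs)]; ys <- ys[is.finite(ys)]
    if (length(xs) < 2 || length(ys) < 2) return(NULL)
    mw <- mann_whitney(xs, ys)
    data.frame(
      metabolite = met,
      mean_case = mean(xs), sem_case = stats::sd(xs) / sqrt(length(xs)),
      mean_ctrl = mean(ys), sem_ctrl = stats::sd(ys) / sqrt(length(ys)),
      U = mw$U, p = mw$p,
      fc = fold_change(mean(xs), mean(ys)),
      stringsAsFactors = FALSE
    )
  })
  dropped <- colnames(m)[vapply(res, is.null, logical(1))]
  if (length(dropped))
    warning("dropped metabolites with < 2 finite values per group: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  out$q <- bh_adjust(out$p)
  out$significant_raw <- out$p < 0.05
  out$significant_fdr <- out$q < 0.05
  rownames(out) <- NULL
  attr(out, "case") <- case
  attr(out, "control") <- ctrl
  attr(out, "n_raw_discoveries") <- sum(out$significant_raw)
  attr(out, "n_fdr_discoveries") <- sum(out$significant_fdr)
  class(out) <- c("univariate_result", "data.frame")
  out
}

#' Volcano selection of differential metabolites
#'
#' Selects metabolites with a two-sided fold-change threshold (FC >= fc_min
#' or FC <= 1/fc_min) and q below fdr_max, recording the direction relative
#' to the case group.
#'
#' @param result a `univariate_result` from [screen_features()], or any
#'   data.frame with columns `metabolite`, `fc`, `q`.
#' @param fc_min minimal fold change, inclusive (default 2).
#' @param fdr_max maximal q, exclusive (default 0.1).
#' @return data.frame with columns `metabolite`, `fc`, `q`, `selected`,
#'   `direction` (`"up"`, `"down"`, or `NA` when not selected).
#' @export
volcano_select <- function(result, fc_min = 2, fdr_max = 0.1) {
  stopifnot(all(c("metabolite", "fc", "q") %in% names(result)))
  up <- result$fc >= fc_min
  down <- result$fc <= 1 / fc_min
  sel <- (up | down) & result$q < fdr_max
  data.frame(
    metabolite = result$metabolite, fc = result$fc, q = result$q,
    selected = sel,
    direction = ifelse(sel, ifelse(up, "up", "down"), NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Fasting-state insulin resistance and sensitivity indices
#'
#' HOMA-IR = (glucose/18) * insulin / 22.5 and HOMA-beta =
#' 20 * insulin / (glucose/18 - 3.5), with fasting glucose in mg/dL
#' (converted to mmol/L by /18) and insulin in ug/L as assayed;
#' R-QUICKI = 1 / (log10(glucose) + log10(insulin) + log10(NEFA)).
#' HOMA-beta is undefined (returned `NA`) when glucose/18 <= 3.5.
#'
#' @param glucose_mg_dl fasting glucose, mg/dL.
#' @param insulin_ug_l fasting insulin, ug/L.
#' @param nefa_mmol_l fasting non-esterified fatty acids, mmol/L (only used
#'   by R-QUICKI; may be omitted).
#' @return list with `homa_ir`, `homa_beta`, `r_quicki` (all dimensionless).
#' @export
clinical_indices <- function(glucose_mg_dl, insulin_ug_l, nefa_mmol_l = NULL) {
  if (any(glucose_mg_dl <= 0) || any(insulin_ug_l <= 0))
    stop("glucose and insulin must be positive")
  g_mm <- glucose_mg_dl / 18
  homa_ir <- g_mm * insulin_ug_l / 22.5
  homa_beta <- ifelse(g_mm > 3.5, 20 * insulin_ug_l / (g_mm - 3.5), NA_real_)
  r_quicki <- if (is.null(nefa_mmol_l)) NULL else {
    if (any(nefa_mmol_l <= 0)) stop("NEFA must be positive")
    1 / (log10(glucose_mg_dl) + log10(insulin_ug_l) + log10(nefa_mmol_l))
  }
  list(homa_ir = homa_ir, homa_beta = homa_beta, r_quicki = r_quicki)
}
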