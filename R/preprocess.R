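#' QC-anchored run-day block normalization
#'
#' Corrects multiplicative inter-day instrument drift: within each run-day
#' block, every value of a metabolite is multiplied by the ratio of the
#' global QC mean to that block's QC mean, so QC means become equal across
#' blocks. Metabolites whose QC mean is zero (or all-missing) in some block
#' cannot be anchored and are dropped, with the drop recorded in the report.
#'
#' @param table a [feature_table()] with at least one QC sample per block.
#' @return list with `table` (corrected `feature_table`) and `report`
#'   (list: `factors` blocks-x-metabolites matrix of applied factors,
#'   `dropped` character vector, `reason` named character).
#' @export
qc_block_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  blocks <- table$meta$block
  ub <- sort(unique(blocks))
  for (b in ub) {
    if (!any(table$meta$is_qc[blocks == b]))
      stop("block ", b, " contains no QC sample; cannot anchor correction")
  }
  ab <- table$abundance
  qc <- table$meta$is_qc
  p <- ncol(ab)

  block_qc_mean <- matrix(NA_real_, length(ub), p,
                          dimnames = list(as.character(ub), colnames(ab)))
  for (i in seq_along(ub)) {
    rows <- qc & blocks == ub[i]
    block_qc_mean[i, ] <- colMeans(ab[rows, , drop = FALSE], na.rm = TRUE)
  }
  global_qc_mean <- colMeans(ab[qc, , drop = FALSE], na.rm = TRUE)

  bad <- apply(block_qc_mean, 2, function(v) any(!is.finite(v) | v <= 0)) |
    !is.finite(global_qc_mean) | global_qc_mean <= 0
  dropped <- colnames(ab)[bad]
  factors <- sweep(1 / block_qc_mean[, !bad, drop = FALSE], 2,
                   global_qc_mean[!bad], `*`)
  out <- ab[, !bad, drop = FALSE]
  for (i in seq_along(ub)) {
    idx <- blocks == ub[i]
    out[idx, ] <- sweep(out[idx, , drop = FALSE], 2, factors[i, ], `*`)
  }
  list(
    table = feature_table(out, table$meta),
    report = list(
      factors = factors,
      dropped = dropped,
      reason = stats::setNames(rep("non-positive QC mean in some block",
                                   length(dropped)), dropped)
    )
  )
}

#' Probabilistic quotient normalization
#'
#' Divides each sample by the median of its elementwise ratios to a
#' reference spectrum, computed over features positive in both sample and
#' reference; corrects per-sample dilution (urine concentration) while
#' leaving composition intact.
#'
#' @param table a [feature_table()].
#' @param reference `"median"` (default: median spectrum of the non-QC
#'   samples) or a numeric vector of length `ncol(table)` naming an explicit
#'   reference spectrum.
#' @return list with `table` (normalized) and `report` (list:
#'   `coefficients` named per-sample dilution quotients, `reference`).
#' @export
pqn_normalize <- function(table, reference = "median") {
  stopifnot(inherits(table, "feature_table"))
  ab <- table$abundance
  ref <- if (identical(reference, "median")) {
    apply(ab[!table$meta$is_qc, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  } else {
    if (length(reference) != ncol(ab))
      stop("explicit reference must have one value per metabolite")
    as.numeric(reference)
  }
  if (mean(ref > 0, na.rm = TRUE) <= 0.5)
    stop("reference spectrum must be positive for more than half the features")
  coef <- numeric(nrow(ab))
  names(coef) <- rownames(ab)
  for (i in seq_len(nrow(ab))) {
    ok <- which(ab[i, ] > 0 & ref > 0 & is.finite(ab[i, ]) & is.finite(ref))
    if (length(ok) < 3)
      stop("sample ", rownames(ab)[i],
           " shares fewer than 3 positive features with the reference")
    coef[i] <- stats::median(ab[i, ok] / ref[ok])
  }
  list(
    table = feature_table(ab / coef, table$meta),
    report = list(coefficients = coef, reference = ref)
  )
}

#' Column-wise z-scoring
#'
#' Centers each metabolite to mean zero and scales to unit sample standard
#' deviation (n - 1 divisor).
#'
#' @param table a [feature_table()] or plain numeric matrix.
#' @return Object of the same kind with standardized columns.
#' @export
zscore_columns <- function(table) {
  m <- if (inherits(table, "feature_table")) table$abundance else as.matrix(table)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop("constant column(s): ",
         paste(colnames(m)[!is.finite(sds) | sds == 0], collapse = ", "))
  z <- scale(m, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  if (inherits(table, "feature_table")) {
    # z-scores are signed; bypass the non-negativity gate of the constructor
    out <- table
    out$abundance <- z
    out
  } else z
}
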