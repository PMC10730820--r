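#' Samples-by-metabolites feature table
#'
#' A feature table couples a non-negative abundance matrix (samples in rows,
#' metabolites in columns, semi-quantified internal-standard response ratios)
#' with per-sample metadata: cohort, group label, run-day block and a QC flag.
#' Missing abundances are encoded as `NA`, never as silent zeros.
#'
#' @param abundance numeric matrix, samples x metabolites, with unique
#'   rownames (sample ids) and colnames (metabolite names).
#' @param meta data.frame with one row per sample and columns `sample_id`,
#'   `cohort`, `group`, `block`, `is_qc`. Row order must match `abundance`.
#' @return An object of class `feature_table`: a list with elements
#'   `abundance` and `meta`.
#' @export
feature_table <- function(abundance, meta) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix must carry sample ids (rownames) and metabolite names (colnames)")
  if (anyDuplicated(rownames(abundance)))
    stop("sample ids must be unique")
  if (anyDuplicated(colnames(abundance)))
    stop("metabolite names must be unique")
  if (any(abundance < 0, na.rm = TRUE))
    stop("negative abundances are not allowed in a feature table")
  required <- c("sample_id", "cohort", "group", "block", "is_qc")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("meta is missing columns: ", paste(missing_cols, collapse = ", "))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(abundance))
    stop("meta has ", nrow(meta), " rows but abundance has ", nrow(abundance))
  if (!identical(as.character(meta$sample_id), rownames(abundance)))
    stop("meta$sample_id must match abundance rownames in order")
  meta$is_qc <- as.logical(meta$is_qc)
  structure(list(abundance = abundance, meta = meta), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d samples x %d metabolites (%d QC)\n",
    nrow(x$abundance), ncol(x$abundance), sum(x$meta$is_qc)
  ))
  grp <- table(x$meta$group[!x$meta$is_qc])
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$abundance)

#' Subset a feature table by samples and/or metabolites
#'
#' @param x a `feature_table`.
#' @param samples logical/integer/character index over samples.
#' @param features logical/integer/character index over metabolites.
#' @return A `feature_table` restricted to the requested rows/columns.
#' @export
ft_subset <- function(x, samples = NULL, features = NULL) {
  stopifnot(inherits(x, "feature_table"))
  ab <- x$abundance
  meta <- x$meta
  if (!is.null(samples)) {
    ab <- ab[samples, , drop = FALSE]
    meta <- meta[match(rownames(ab), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (!is.null(features)) ab <- ab[, features, drop = FALSE]
  feature_table(ab, meta)
}

#' Abundance matrix of the non-QC study samples
#'
#' @param x a `feature_table`.
#' @return Numeric matrix restricted to samples with `is_qc == FALSE`.
#' @export
ft_study_matrix <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  x$abundance[!x$meta$is_qc, , drop = FALSE]
}

#' Group labels of the non-QC study samples
#'
#' @param x a `feature_table`.
#' @return Character vector of group labels, one per study sample.
#' @export
ft_study_groups <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  as.character(x$meta$group[!x$meta$is_qc])
}

#' Write a feature table to CSV
#'
#' Layout: one row per sample; columns `sample_id`, `cohort`, `group`,
#' `block`, `is_qc`, then one column per metabolite (names verbatim).
#'
#' @param x a `feature_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  out <- cbind(x$meta, as.data.frame(x$abundance, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path file path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("sample_id", "cohort", "group", "block", "is_qc")
  missing_cols <- setdiff(meta_cols, names(df))
  if (length(missing_cols))
    stop("not a feature-table CSV; missing columns: ",
         paste(missing_cols, collapse = ", "))
  ab <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(ab) <- df$sample_id
  feature_table(ab, df[meta_cols])
}
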