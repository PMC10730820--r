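#' Group-wise cohort summary with significance tests
#'
#' Tabulates mean and SEM per group for every numeric variable and attaches
#' a two-group p-value: Welch's t-test for clinical/biometric variables (the
#' convention for cohort characteristics tables) or Mann-Whitney for
#' metabolite-derived variables. Zero-variance variables get `NA` with a
#' warning.
#'
#' @param data data.frame of numeric variables (non-numeric columns are
#'   ignored).
#' @param groups two-group label vector, one per row.
#' @param test `"t"` (Welch, default) or `"mw"`.
#' @return data.frame with one row per variable: per-group mean, SEM, and
#'   `p`.
#' @export
cohort_summary <- function(data, groups, test = c("t", "mw")) {
  test <- match.arg(test)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  if (min(table(groups)) < 2) stop("each group needs at least 2 rows")
  num <- data[vapply(data, is.numeric, logical(1))]
  rows <- lapply(names(num), function(v) {
    a <- num[[v]][groups == lv[1]]
    b <- num[[v]][groups == lv[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      warning("zero variance in both groups for ", v, "; p set to NA")
      NA_real_
    } else if (test == "t") {
      stats::t.test(a, b)$p.value
    } else {
      mann_whitney(a, b)$p
    }
    out <- data.frame(
      variable = v,
      mean_1 = mean(a), sem_1 = stats::sd(a) / sqrt(length(a)),
      mean_2 = mean(b), sem_2 = stats::sd(b) / sqrt(length(b)),
      p = p, stringsAsFactors = FALSE
    )
    names(out)[2:5] <- c(paste0("mean_", lv[1]), paste0("sem_", lv[1]),
                         paste0("mean_", lv[2]), paste0("sem_", lv[2]))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble and write a machine-readable run report
#'
#' Collects the per-stage summaries of a pipeline run (configuration echo,
#' diagnostics, verdicts, counts) into one JSON document. Regenerating the
#' report from the same inputs, configuration and seed yields identical
#' scientific content.
#'
#' @param stages named list of stage summaries (any JSON-serializable
#'   structure).
#' @param config named list echoing every numeric default used.
#' @param path optional output path; when given, the report is written as
#'   JSON.
#' @return The report list, invisibly when written.
#' @export
run_report <- function(stages, config = list(), path = NULL) {
  report <- list(
    package = "metabotrans",
    version = as.character(utils::packageVersion("metabotrans")),
    config = config,
    stages = stages
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(report))
  }
  report
}
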