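# Core data containers: beta matrices (BS/oxBS methylation arrays) and count
# matrices (nascent-transcription / RNA-seq features), each carrying a sample
# sheet (sample, condition, replicate).

validate_sample_sheet <- function(sheet, n_col = NULL) {
  need <- c("sample", "condition", "replicate")
  if (!is.data.frame(sheet) || !all(need %in% names(sheet))) {
    stopf("sample sheet must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample)) stopf("duplicated sample ids in sample sheet")
  if (!is.null(n_col) && nrow(sheet) != n_col) {
    stopf("sample sheet has %d rows but matrix has %d columns",
          nrow(sheet), n_col)
  }
  sheet$sample <- as.character(sheet$sample)
  sheet$condition <- as.character(sheet$condition)
  sheet
}

#' Build a sample design sheet
#'
#' @param conditions Character vector of condition labels, in order.
#' @param replicates Number of replicates per condition.
#' @return A data.frame with columns `sample`, `condition`, `replicate`;
#'   sample ids are `<condition>_r<replicate>`.
#' @export
make_design <- function(conditions, replicates) {
  stopifnot(length(conditions) >= 1, replicates >= 1)
  data.frame(
    sample = paste0(rep(conditions, each = replicates), "_r",
                    rep(seq_len(replicates), length(conditions))),
    condition = rep(conditions, each = replicates),
    replicate = rep(seq_len(replicates), length(conditions)),
    stringsAsFactors = FALSE
  )
}

#' Methylation beta-value matrix
#'
#' A probe x sample matrix of beta values in \[0, 1\] from one assay (BS reads
#' 5mC + 5hmC; oxBS reads 5mC only), with its sample design attached.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). Values in \[0, 1\] or `NA`.
#' @param sample_sheet data.frame with columns `sample`, `condition`,
#'   `replicate`, one row per matrix column (matched by `sample`).
#' @param assay `"BS"` or `"oxBS"`.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, sample_sheet, assay = c("BS", "oxBS")) {
  assay <- match.arg(assay)
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("'values' must be a matrix with probe rownames and sample colnames")
  }
  sheet <- validate_sample_sheet(sample_sheet, ncol(values))
  if (!setequal(sheet$sample, colnames(values))) {
    stopf("sample sheet ids do not match matrix column names")
  }
  sheet <- sheet[match(colnames(values), sheet$sample), , drop = FALSE]
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stopf("beta values must lie in [0, 1]")
  structure(list(values = values, samples = sheet, assay = assay),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix [%s]: %d probes x %d samples (%s)\n", x$assay,
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$condition), collapse = ", ")))
  invisible(x)
}

#' Subset a beta matrix by condition
#'
#' @param x A [beta_matrix()].
#' @param conditions Condition labels to keep.
#' @return A `beta_matrix` restricted to the matching samples.
#' @export
subset_conditions <- function(x, conditions) {
  stopifnot(inherits(x, "beta_matrix"))
  keep <- x$samples$condition %in% conditions
  if (!any(keep)) stopf("no samples match conditions: %s",
                        paste(conditions, collapse = ", "))
  beta_matrix(x$values[, x$samples$sample[keep], drop = FALSE],
              x$samples[keep, , drop = FALSE], x$assay)
}

#' Feature count matrix
#'
#' Non-negative integer counts per feature and sample, with the sample design
#' and a feature kind (`gene` or `eRNA`) used to pick default significance
#' thresholds downstream.
#'
#' @param counts Integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param sample_sheet data.frame with columns `sample`, `condition`,
#'   `replicate`.
#' @param feature_kind `"gene"` or `"eRNA"`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, sample_sheet, feature_kind = c("gene", "eRNA")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("'counts' must be a matrix with feature rownames and sample colnames")
  }
  if (any(counts < 0, na.rm = TRUE)) stopf("counts must be non-negative")
  if (any(counts != round(counts), na.rm = TRUE)) stopf("counts must be integers")
  sheet <- validate_sample_sheet(sample_sheet, ncol(counts))
  if (!setequal(sheet$sample, colnames(counts))) {
    stopf("sample sheet ids do not match count matrix column names")
  }
  sheet <- sheet[match(colnames(counts), sheet$sample), , drop = FALSE]
  structure(list(counts = counts, samples = sheet, feature_kind = feature_kind),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d features x %d samples\n", x$feature_kind,
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
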