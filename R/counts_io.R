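#' Read a raw count matrix from a delimited text file
#'
#' Reads a genes x samples matrix of raw RNA-seq read counts. The first
#' column must hold gene identifiers and the header row sample identifiers;
#' every body cell must parse as a non-negative integer.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field separator, default tab.
#' @return A numeric matrix (genes as rows, samples as columns) with unique
#'   `rownames` (gene ids) and `colnames` (sample ids).
#' @seealso [write_counts()], [filter_low_expression()],
#'   [estimate_size_factors()]
#' @export
read_counts <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("count file does not exist: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 1L) stop("malformed header: no columns parsed from ", path)
  gene_ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  colnames(m) <- sample_ids
  validate_counts(m)
  m
}

#' Write a count matrix to a delimited text file
#'
#' Inverse of [read_counts()]: the written file round-trips to an identical
#' matrix.
#'
#' @param m Count matrix (genes x samples, named dims).
#' @param path Output path.
#' @param delimiter Field separator, default tab.
#' @export
write_counts <- function(m, path, delimiter = "\t") {
  validate_counts(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write counts to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Validate a raw count matrix
#'
#' Checks the count-matrix contract: a numeric matrix of finite,
#' non-negative, integral values with unique gene (row) and sample (column)
#' identifiers.
#'
#' @param m Matrix to check.
#' @return `m`, invisibly, if valid; otherwise an error naming the offender.
#' @export
validate_counts <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("counts must be a numeric matrix")
  if ((is.null(rownames(m)) && nrow(m) > 0) ||
      (is.null(colnames(m)) && ncol(m) > 0))
    stop("counts must carry gene ids as rownames and sample ids as colnames")
  dg <- rownames(m)[duplicated(rownames(m))]
  if (length(dg)) stop("duplicated gene id(s): ", paste(unique(dg), collapse = ", "))
  ds <- colnames(m)[duplicated(colnames(m))]
  if (length(ds)) stop("duplicated sample id(s): ", paste(unique(ds), collapse = ", "))
  bad <- which(!is.finite(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-negative integer counts required; first offending cell: gene '",
         rownames(m)[bad[1, 1]], "', sample '", colnames(m)[bad[1, 2]], "'")
  }
  invisible(m)
}

#' Remove genes with low mean expression
#'
#' Keeps exactly the genes whose mean raw count across samples is at least
#' `min_mean`. Lowly expressed genes carry almost no signal for
#' reconstruction-based outlier detection and inflate the model input, so
#' they are dropped before fitting.
#'
#' @param m Count matrix.
#' @param min_mean Minimum mean raw count (default 1).
#' @return The filtered matrix; attributes `n_retained` and `n_removed`
#'   record the gene bookkeeping.
#' @export
filter_low_expression <- function(m, min_mean = 1) {
  validate_counts(m)
  stopifnot(is.numeric(min_mean), length(min_mean) == 1L, min_mean >= 0)
  keep <- rowMeans(m) >= min_mean
  if (!any(keep))
    stop("no gene passes min_mean = ", min_mean,
         "; lower the filtering threshold")
  out <- m[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Estimate per-sample size factors (median-of-ratios)
#'
#' DESeq-style median-of-ratios estimate of sequencing depth: each sample's
#' counts are divided by the per-gene geometric-mean pseudo-reference and the
#' median ratio over genes with all-positive counts is taken. Factors are
#' rescaled to have geometric mean exactly 1 so that the normalization
#' carries no global scale.
#'
#' @param m Count matrix.
#' @return Named numeric vector of positive size factors, one per sample,
#'   geometric mean 1.
#' @export
estimate_size_factors <- function(m) {
  validate_counts(m)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no gene has positive counts in every sample; ",
         "filter low-expression genes or check the input")
  lg <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(lg)             # per-gene log geometric mean
  sf <- exp(apply(lg - ref, 2L, stats::median))
  sf <- sf / exp(mean(log(sf)))   # geometric mean 1
  names(sf) <- colnames(m)
  sf
}

#' Read a sample covariate table
#'
#' A delimited table whose first column holds sample ids and remaining
#' columns categorical covariates (e.g. sex, batch).
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field separator, default tab.
#' @return A data.frame with a `sample_id` column and factor covariates.
#' @export
read_covariates <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("covariate file does not exist: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample id(s) in covariate table")
  for (j in seq_along(df)[-1L]) df[[j]] <- factor(df[[j]])
  df
}
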