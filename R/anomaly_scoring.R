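#' Isolation-forest anomaly scores for a point cloud
#'
#' Standard isolation forest: an ensemble of random partition trees grown on
#' subsamples; points isolated in fewer random splits receive scores nearer
#' 1. The score is `2^(-E[h(x)] / c(m))` where `E[h(x)]` averages the path
#' length over trees and `c(m)` is the expected unsuccessful-search path
#' length of a binary search tree over the `m` subsampled points (exact
#' harmonic numbers, so `c(2) = 1`).
#'
#' @param points Numeric matrix, one row per observation (here usually the
#'   2-column (divergence, delta) cloud of one gene).
#' @param n_trees Number of trees (default 100).
#' @param subsample Subsample size per tree (default `min(64, n)`).
#' @param seed Integer seed; scores are deterministic given the seed.
#' @return Numeric vector of anomaly scores, strictly inside (0, 1).
#' @export
isolation_scores <- function(points, n_trees = 100L,
                             subsample = min(64L, nrow(points)),
                             seed = 1L) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("isolation forest needs at least 2 points")
  if (any(!is.finite(points))) {
    # sentinel infinities are as anomalous as numbers get; clamp for splits
    points <- pmin(pmax(points, -1e12), 1e12)
  }
  set.seed(seed)
  iso_forest_scores_cpp(points, as.integer(n_trees), as.integer(subsample))
}

#' Expected isolation path-length normalizer
#'
#' `c(m) = 2 H(m - 1) - 2 (m - 1) / m` with exact harmonic numbers; the
#' denominator of the isolation-forest score exponent.
#'
#' @param m Subsample size.
#' @return The normalizing constant.
#' @export
iso_path_norm <- function(m) iso_path_norm_cpp(as.integer(m))

#' Score classified observations with per-gene isolation forests
#'
#' Runs an isolation forest on each gene's (divergence, delta) point cloud
#' across samples and attaches the anomaly score to every observation.
#' Scores are computed for all points — labels only govern reporting — and
#' the result is sorted AGE-first by descending score, so the top rows are
#' the most severe calls. Genes with fewer than 2 samples are excluded and
#' recorded in the `excluded_genes` attribute.
#'
#' @param scores A `score_pair`.
#' @param labels Classification from [classify_observations()] (data.frame
#'   with gene_id, sample_id, label).
#' @param n_trees,subsample Forest size per gene (defaults 100 trees,
#'   subsample `min(64, n_samples)`).
#' @param seed Integer seed for the whole sweep.
#' @return Data.frame of class `age_calls` with columns gene_id, sample_id,
#'   label, anomaly_score, divergence, delta.
#' @export
score_calls <- function(scores, labels, n_trees = 100L, subsample = NULL,
                        seed = 1L) {
  stopifnot(inherits(scores, "score_pair"))
  ns <- length(scores$sample_ids)
  if (is.null(subsample)) subsample <- min(64L, ns)
  excluded <- character(0)
  if (ns < 2L) {
    excluded <- scores$gene_ids
    stop("fewer than 2 samples; isolation scoring impossible")
  }
  genes <- unique(labels$gene_id)
  gidx <- match(genes, scores$gene_ids)
  if (anyNA(gidx)) stop("labels refer to genes absent from the score pair")

  set.seed(seed)
  score_mat <- matrix(NA_real_, length(genes), ns,
                      dimnames = list(genes, scores$sample_ids))
  for (i in seq_along(genes)) {
    pts <- cbind(scores$divergence[gidx[i], ], scores$delta[gidx[i], ])
    pts <- pmin(pmax(pts, -1e12), 1e12)
    score_mat[i, ] <- iso_forest_scores_cpp(pts, as.integer(n_trees),
                                            as.integer(min(subsample, ns)))
  }
  idx <- cbind(match(labels$gene_id, genes),
               match(labels$sample_id, scores$sample_ids))
  out <- data.frame(
    gene_id = labels$gene_id, sample_id = labels$sample_id,
    label = labels$label,
    anomaly_score = score_mat[idx],
    divergence = scores$divergence[cbind(match(labels$gene_id, scores$gene_ids),
                                         idx[, 2L])],
    delta = scores$delta[cbind(match(labels$gene_id, scores$gene_ids),
                               idx[, 2L])],
    stringsAsFactors = FALSE)
  out <- out[order(out$label != "AGE", -out$anomaly_score), ]
  rownames(out) <- NULL
  class(out) <- c("age_calls", "data.frame")
  attr(out, "excluded_genes") <- excluded
  out
}

#' Write an AGE call set as TSV
#'
#' @param calls An `age_calls` data.frame.
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
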