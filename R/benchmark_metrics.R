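#' Confusion counts of AGE calls against injection ground truth
#'
#' A call counts as a true positive only on an exact (gene, sample) match
#' with an injected entry; injections that rounding/clipping collapsed back
#' to the original value are undetectable in principle and should be
#' removed from the mask first (see [effective_truth_mask()]).
#'
#' @param pred An `age_calls` data.frame (or any data.frame with gene_id,
#'   sample_id, label).
#' @param truth Logical genes x samples injection mask.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(is.matrix(truth), is.logical(truth))
  if (!all(pred$gene_id %in% rownames(truth)) ||
      !all(pred$sample_id %in% colnames(truth)))
    stop("prediction universe not covered by the truth mask")
  pos <- pred[pred$label == "AGE", , drop = FALSE]
  key <- function(g, s) paste(g, s, sep = "\r")
  pred_set <- key(pos$gene_id, pos$sample_id)
  inj <- which(truth, arr.ind = TRUE)
  truth_set <- key(rownames(truth)[inj[, 1L]], colnames(truth)[inj[, 2L]])
  tp <- sum(pred_set %in% truth_set)
  fp <- length(pred_set) - tp
  fn <- length(truth_set) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
          2 * precision * recall / (precision + recall) else 0
  if (tp == 0) f1 <- 0
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}

#' Drop undetectable injections from a truth mask
#'
#' Injections whose rounded replacement equals the original count leave no
#' trace in the data; they are removed from the ground truth before scoring.
#'
#' @param ds A `labeled_dataset`.
#' @return Logical mask of detectable injections.
#' @export
effective_truth_mask <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  ds$mask & (ds$corrupted != ds$original)
}

#' Precision-recall curve over ranked calls
#'
#' Sweeps a threshold over the chosen ranking score in descending order of
#' |score| (anomaly scores are already in (0, 1) so the absolute value is a
#' no-op there) and emits one (recall, precision) point per distinct score;
#' tied scores enter as a block.
#'
#' @param calls Data.frame with gene_id, sample_id and the ranking columns
#'   (divergence, delta, anomaly_score).
#' @param truth Logical genes x samples injection mask; must contain at
#'   least one injection.
#' @param ranking `"divergence"`, `"delta"` or `"anomaly"`.
#' @return Data.frame (threshold, recall, precision) of class `pr_curve`;
#'   recalls are non-decreasing.
#' @export
pr_curve <- function(calls, truth,
                     ranking = c("divergence", "delta", "anomaly")) {
  ranking <- match.arg(ranking)
  stopifnot(is.matrix(truth), is.logical(truth))
  n_pos <- sum(truth)
  if (n_pos == 0L)
    stop("truth mask contains no injections; recall undefined")
  col <- switch(ranking, divergence = "divergence", delta = "delta",
                anomaly = "anomaly_score")
  if (is.null(calls[[col]]))
    stop("calls lack the ranking column ", col)
  s <- abs(calls[[col]])
  idx <- cbind(match(calls$gene_id, rownames(truth)),
               match(calls$sample_id, colnames(truth)))
  if (anyNA(idx)) stop("calls outside the truth universe")
  is_pos <- truth[idx]

  ord <- order(-s)
  s <- s[ord]; is_pos <- is_pos[ord]
  # block ties: cumulative counts at the last index of each distinct score
  last <- which(!duplicated(s, fromLast = TRUE))
  ctp <- cumsum(is_pos)[last]
  cn <- last
  out <- data.frame(threshold = s[last],
                    recall = ctp / n_pos,
                    precision = ctp / cn)
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Area under a precision-recall curve
#'
#' Step-function integral (average precision over the recall increments),
#' matching an exhaustive all-thresholds computation exactly.
#'
#' @param curve A `pr_curve`.
#' @return Scalar area in `[0, 1]`.
#' @export
pr_auc <- function(curve) {
  r <- c(0, curve$recall)
  sum(curve$precision * diff(r))
}

#' Run the semi-synthetic benchmark over a dataset grid
#'
#' For each labeled dataset: trains the full detector on the corrupted
#' counts (supervised phase, using the dataset's own injection labels),
#' classifies, scores, and evaluates against the detectable injections.
#' Per-dataset failures are caught and reported without aborting the run.
#'
#' @param grid List of `labeled_dataset` objects (see
#'   [build_benchmark_grid()]).
#' @param config An [agescan_config()] applied to every dataset.
#' @param rankings Which precision-recall rankings to trace.
#' @param verbose Print one progress line per dataset.
#' @return List of `benchmark_result` lists (provenance, tp/fp/fn,
#'   precision/recall/f1, `pr_curves`, `error` when a dataset failed).
#' @export
run_benchmark <- function(grid, config = agescan_config(),
                          rankings = c("divergence", "delta", "anomaly"),
                          verbose = TRUE) {
  stopifnot(length(grid) > 0)
  lapply(seq_along(grid), function(i) {
    ds <- grid[[i]]
    prov <- attr(ds, "provenance")
    res <- tryCatch({
      fit <- agescan(ds$corrupted, mask = ds$mask, config = config)
      truth <- effective_truth_mask(ds)
      truth <- truth[rownames(truth) %in% unique(fit$calls$gene_id), ,
                     drop = FALSE]
      cm <- confusion_counts(fit$calls, truth)
      curves <- if (sum(truth) > 0)
        stats::setNames(lapply(rankings, function(r)
          pr_curve(fit$calls, truth, r)), rankings)
      else list()
      c(list(provenance = prov), cm, list(pr_curves = curves, error = NULL))
    }, error = function(e) {
      list(provenance = prov, tp = NA, fp = NA, fn = NA, precision = NA,
           recall = NA, f1 = NA, pr_curves = list(),
           error = conditionMessage(e))
    })
    if (verbose) {
      msg <- if (is.null(res$error))
        sprintf("dataset %d: recall %.3f precision %.3f", i,
                res$recall, res$precision)
      else sprintf("dataset %d failed: %s", i, res$error)
      message(msg)
    }
    structure(res, class = "benchmark_result")
  })
}

#' Tabulate a list of benchmark results
#'
#' @param results List returned by [run_benchmark()].
#' @return Data.frame with one row per dataset (size, probability, counts
#'   and scores).
#' @export
benchmark_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(size = r$provenance$size %||% NA,
               probability = r$provenance$probability %||% NA,
               tp = r$tp, fp = r$fp, fn = r$fn,
               precision = r$precision, recall = r$recall, f1 = r$f1,
               error = r$error %||% "", stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
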