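#' Configuration of an aberrant-expression detection run
#'
#' Bundles every tunable of the pipeline. A single `seed` is fanned out to
#' the stages by fixed offsets (VAE +101, tree +202, forest +303) so each
#' stage is individually reproducible.
#'
#' @param filter_min_mean Low-expression filter: minimum mean raw count per
#'   gene (default 1).
#' @param vae A [vae_config()]; its seed is overridden by the derived one.
#' @param score_axis Standardization axis of the divergence score.
#' @param tree_max_depth,tree_min_leaf,tree_class_weight CART settings for
#'   the supervised phase.
#' @param forest_trees,forest_subsample Isolation-forest settings
#'   (`forest_subsample = NULL` means `min(64, n_samples)`).
#' @param relax_tau Optional AGE-purity relaxation threshold for
#'   classification (see [classify_observations()]).
#' @param seed Global integer seed.
#' @return An object of class `agescan_config`.
#' @export
agescan_config <- function(filter_min_mean = 1, vae = vae_config(),
                           score_axis = c("per_gene", "per_sample"),
                           tree_max_depth = 6L, tree_min_leaf = 20L,
                           tree_class_weight = "balanced",
                           forest_trees = 100L, forest_subsample = NULL,
                           relax_tau = NULL, seed = 1L) {
  structure(list(filter_min_mean = filter_min_mean, vae = vae,
                 score_axis = match.arg(score_axis),
                 tree_max_depth = as.integer(tree_max_depth),
                 tree_min_leaf = as.integer(tree_min_leaf),
                 tree_class_weight = tree_class_weight,
                 forest_trees = as.integer(forest_trees),
                 forest_subsample = forest_subsample,
                 relax_tau = relax_tau, seed = as.integer(seed)),
            class = "agescan_config")
}

#' Detect aberrant gene expression in a count matrix
#'
#' The full detector: filter low-expression genes, estimate size factors,
#' train the variational autoencoder on the (possibly corrupted) counts,
#' reconstruct, compute the divergence-score / delta-count pair, derive the
#' per-gene regression influence diagnostics, classify each (gene, sample)
#' point as AGE or NGE, and rank calls with per-gene isolation-forest
#' anomaly scores.
#'
#' Two modes share this interface:
#'
#' * **Supervised** (`mask` supplied): the injection mask of a
#'   semi-synthetic dataset labels the diagnostics, a CART tree is trained
#'   and its interval rules are both applied and returned — this is how the
#'   shipped default rules were produced.
#' * **Unsupervised** (`mask = NULL`): previously learned `intervals`
#'   (default: the packaged synthetic-trained rules) classify the cohort.
#'
#' @param counts Count matrix (genes x samples) or a path readable by
#'   [read_counts()].
#' @param size_factors Optional per-sample size factors; estimated by
#'   median-of-ratios when `NULL`.
#' @param mask Optional logical genes x samples injection mask enabling the
#'   supervised phase.
#' @param intervals `age_intervals` used for classification when no mask is
#'   given; `NULL` falls back to [default_intervals()].
#' @param config An [agescan_config()].
#' @return An object of class `agescan`; see [print.agescan()],
#'   [summary.agescan()], [fitted.agescan()], [residuals.agescan()],
#'   [predict.agescan()] and [plot.agescan()].
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(40, 300, seed = 7))
#' inj <- inject_aberrations(cohort$counts, injection_params(2e-3, seed = 8),
#'                           cohort$size_factors)
#' cfg <- agescan_config(vae = vae_config(latent_dim = 8,
#'                                        hidden_sizes = c(64, 32, 24, 16),
#'                                        epochs = 60, seed = 1))
#' fit <- agescan(inj$corrupted, mask = inj$mask, config = cfg)
#' print(fit)
#' head(subset(fit$calls, label == "AGE"))
#' }
#' @export
agescan <- function(counts, size_factors = NULL, mask = NULL,
                    intervals = NULL, config = agescan_config()) {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(counts)) counts <- read_counts(counts)
  validate_counts(counts)
  n_genes_in <- nrow(counts)

  filtered <- filter_low_expression(counts, config$filter_min_mean)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(counts)))
    dimnames(mask) <- dimnames(counts)
    mask <- mask[rownames(filtered), , drop = FALSE]
  }
  sf <- if (is.null(size_factors)) estimate_size_factors(filtered)
        else size_factors[colnames(filtered)]

  vcfg <- config$vae
  vcfg$seed <- config$seed + 101L
  feats <- preprocess_counts(filtered, sf)
  model <- build_vae(vcfg, nrow(filtered))
  model <- train_vae(model, feats, vcfg)
  recon <- reconstruct_counts(model, feats)
  latent <- encode_latent(model, feats)

  scores <- score_pair(filtered, recon, config$score_axis)
  diag <- regression_diagnostics(scores)

  tree <- NULL
  if (!is.null(mask)) {
    tree <- train_decision_tree(diag, mask_to_labels(diag, mask),
                                max_depth = config$tree_max_depth,
                                min_leaf = config$tree_min_leaf,
                                class_weight = config$tree_class_weight,
                                seed = config$seed + 202L)
    intervals <- tree$intervals
  } else if (is.null(intervals)) {
    intervals <- default_intervals()
  }
  labels <- classify_observations(diag, intervals,
                                  relax_tau = config$relax_tau)
  calls <- score_calls(scores, labels, n_trees = config$forest_trees,
                       subsample = config$forest_subsample %||%
                                   min(64L, ncol(filtered)),
                       seed = config$seed + 303L)

  structure(list(calls = calls, intervals = intervals, scores = scores,
                 diagnostics = diag, tree = tree, vae = model,
                 latent = latent, reconstruction = recon,
                 counts = filtered, size_factors = sf, config = config,
                 supervised = !is.null(mask), mask = mask,
                 n_genes_in = n_genes_in, n_genes_kept = nrow(filtered),
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "agescan")
}

#' @describeIn agescan Compact overview of a fitted run.
#' @param x,object An `agescan` object.
#' @param ... Unused.
#' @export
print.agescan <- function(x, ...) {
  n_age <- sum(x$calls$label == "AGE")
  cat("Aberrant gene expression scan (",
      if (x$supervised) "supervised" else "unsupervised", " phase)\n",
      sep = "")
  cat("  genes: ", x$n_genes_kept, " kept of ", x$n_genes_in,
      "; samples: ", ncol(x$counts), "\n", sep = "")
  cat("  AGE calls: ", n_age, " of ", nrow(x$calls), " observations (",
      signif(100 * n_age / nrow(x$calls), 3), "%)\n", sep = "")
  cat("  VAE: latent ", x$vae$cfg$latent_dim, ", ",
      length(x$vae$history), " epochs, final loss ",
      signif(utils::tail(x$vae$history, 1), 4), "\n", sep = "")
  cat("  elapsed: ", round(x$elapsed, 1), " s\n", sep = "")
  invisible(x)
}

#' @describeIn agescan Per-sample AGE counts and the top-ranked calls.
#' @param top Number of top calls to show.
#' @export
summary.agescan <- function(object, top = 10L, ...) {
  age <- object$calls[object$calls$label == "AGE", , drop = FALSE]
  per_sample <- table(factor(age$sample_id,
                             levels = colnames(object$counts)))
  out <- list(n_age = nrow(age), per_sample_age = per_sample,
              top_calls = utils::head(age, top),
              excluded = attr(object$diagnostics, "excluded"))
  class(out) <- "summary.agescan"
  out
}

#' @export
print.summary.agescan <- function(x, ...) {
  cat("AGE calls:", x$n_age, "\n")
  cat("Per-sample AGE counts (nonzero):\n")
  nz <- x$per_sample_age[x$per_sample_age > 0]
  if (length(nz)) print(nz) else cat("  none\n")
  if (nrow(x$top_calls)) {
    cat("Top calls by anomaly score:\n")
    print(x$top_calls, row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn agescan Reconstructed counts (genes x samples).
#' @export
fitted.agescan <- function(object, ...) object$reconstruction

#' @describeIn agescan Count-scale residuals, observed minus reconstructed.
#' @export
residuals.agescan <- function(object, ...)
  object$counts - object$reconstruction

#' @describeIn agescan Classify a new diagnostics table with the run's
#'   interval rules.
#' @param newdata A `diagnostics_table`.
#' @export
predict.agescan <- function(object, newdata = object$diagnostics, ...) {
  classify_observations(newdata, object$intervals,
                        relax_tau = object$config$relax_tau)
}

#' @describeIn agescan Divergence-score vs delta-count cloud for one gene,
#'   AGE calls highlighted.
#' @param gene Gene identifier to plot.
#' @export
plot.agescan <- function(x, gene = NULL, ...) {
  if (is.null(gene)) {
    age <- x$calls[x$calls$label == "AGE", , drop = FALSE]
    gene <- if (nrow(age)) age$gene_id[1L] else x$scores$gene_ids[1L]
  }
  j <- match(gene, x$scores$gene_ids)
  if (is.na(j)) stop("unknown gene: ", gene)
  d <- x$scores$divergence[j, ]
  dl <- x$scores$delta[j, ]
  is_age <- x$calls$label[match(paste(gene, x$scores$sample_ids),
                                paste(x$calls$gene_id,
                                      x$calls$sample_id))] == "AGE"
  graphics::plot(d, dl, xlab = "divergence score", ylab = "delta count",
                 main = gene, pch = 19,
                 col = ifelse(is_age, "red", "black"), ...)
  if (any(is_age))
    graphics::legend("topleft", legend = c("AGE", "NGE"), pch = 19,
                     col = c("red", "black"), bty = "n")
  invisible(x)
}

#' Export the latent matrix as TSV
#'
#' One row per sample, one column per latent dimension; suitable for
#' joining with covariates in external exploration tools.
#'
#' @param fit An `agescan` object (or a latent matrix).
#' @param path Output path.
#' @export
write_latent <- function(fit, path) {
  z <- if (inherits(fit, "agescan")) fit$latent else fit
  df <- data.frame(sample_id = rownames(z), z, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the configuration, global seed, package version and (when
#' available) input-file checksums, enough to re-run a phase bit-wise.
#'
#' @param path Output JSON path.
#' @param config An `agescan_config`.
#' @param inputs Named character vector of input file paths to checksum.
#' @param extra Named list appended verbatim.
#' @export
write_manifest <- function(path, config, inputs = character(0),
                           extra = list()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  manifest <- c(list(
    package = "agescan",
    version = as.character(utils::packageVersion("agescan")),
    seed = config$seed,
    config = unclass_rec(config),
    input_md5 = hashes,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else x
}

#' Write an injection mask as a TSV of triples
#'
#' Long-format export of a `labeled_dataset`'s ground truth: one row per
#' injected entry with its direction (up/down).
#'
#' @param ds A `labeled_dataset`.
#' @param path Output path.
#' @export
write_mask <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_dataset"))
  idx <- which(ds$mask, arr.ind = TRUE)
  df <- data.frame(gene_id = rownames(ds$mask)[idx[, 1L]],
                   sample_id = colnames(ds$mask)[idx[, 2L]],
                   direction = ifelse(ds$direction[idx] > 0, "up", "down"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
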