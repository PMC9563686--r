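#' Divergence score between original and reconstructed counts
#'
#' For every (gene, sample) point the count ratio
#' `L_ij = (k_ij + 1) / (k_hat_ij + 1)` is standardized along `axis`:
#' `D_ij = (L_ij - mean(L)) / sd(L)`, by default within each gene across the
#' cohort (population sd, divisor n). A zero sd along an axis yields D = 0
#' there. Faithfully reconstructed points sit near D = 0; points whose
#' reconstruction diverges from the observed count stand out.
#'
#' @param original Count matrix (genes x samples).
#' @param recon Reconstructed counts, same shape (non-negative reals).
#' @param axis `"per_gene"` (default: standardize each gene across samples)
#'   or `"per_sample"`.
#' @return List with `divergence`, the `ratio` matrix L, and the `center`
#'   and `scale` vectors used.
#' @export
divergence_score <- function(original, recon,
                             axis = c("per_gene", "per_sample")) {
  axis <- match.arg(axis)
  check_same_shape(original, recon)
  L <- (original + 1) / (recon + 1)
  if (axis == "per_gene") {
    ctr <- rowMeans(L)
    scl <- row_sds_pop(L)
    D <- (L - ctr) / ifelse(scl == 0, 1, scl)
    D[scl == 0, ] <- 0
  } else {
    ctr <- colMeans(L)
    scl <- row_sds_pop(t(L))
    D <- sweep(sweep(L, 2L, ctr, "-"), 2L, ifelse(scl == 0, 1, scl), "/")
    D[, scl == 0] <- 0
  }
  list(divergence = D, ratio = L, center = ctr, scale = scl, axis = axis)
}

#' Delta count: reconstruction vs the gene's mean expression
#'
#' `Delta_ij = log2((k_hat_ij + 1) / (mu_j + 1))` where `mu_j` is the mean
#' of the gene's original counts across samples. The pseudocount keeps the
#' ratio defined at zero. A reconstruction that tracks an aberrant value
#' rather than the gene's typical level produces a large |Delta|.
#'
#' @param original Count matrix (genes x samples).
#' @param recon Reconstructed counts, same shape.
#' @return Genes x samples matrix of delta counts.
#' @export
delta_count <- function(original, recon) {
  check_same_shape(original, recon)
  mu <- rowMeans(original)
  log2((recon + 1) / (mu + 1))
}

#' Bundle divergence score and delta count
#'
#' The paired reconstruction-fidelity scores every downstream step consumes:
#' per-gene regression diagnostics, classification and anomaly scoring.
#'
#' @inheritParams divergence_score
#' @return An object of class `score_pair` with matrices `divergence`,
#'   `delta`, `ratio`, per-gene `gene_count_means`, the standardization
#'   `ratio_center`/`ratio_scale` and the `axis` used.
#' @export
score_pair <- function(original, recon,
                       axis = c("per_gene", "per_sample")) {
  axis <- match.arg(axis)
  d <- divergence_score(original, recon, axis)
  structure(list(divergence = d$divergence,
                 delta = delta_count(original, recon),
                 ratio = d$ratio,
                 gene_count_means = rowMeans(original),
                 ratio_center = d$center, ratio_scale = d$scale,
                 axis = axis,
                 gene_ids = rownames(original),
                 sample_ids = colnames(original)),
            class = "score_pair")
}

check_same_shape <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
    stop("original and reconstructed matrices must have identical shape")
  if (any(!is.finite(b)) || any(b < 0))
    stop("reconstructed counts must be finite and non-negative")
  invisible(NULL)
}
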