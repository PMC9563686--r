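#' Per-gene regression of delta count on divergence score
#'
#' For one gene, ordinary least squares of the delta counts (response) on
#' the divergence scores (predictor) across samples, with intercept.
#'
#' @param scores A `score_pair`.
#' @param gene_id Gene identifier.
#' @return List of class `gene_regression_fit` with `slope`, `intercept`,
#'   `residual_sd` (divisor n - 2), `n_points` and a `degenerate` flag
#'   (constant predictor).
#' @export
fit_gene_regression <- function(scores, gene_id) {
  stopifnot(inherits(scores, "score_pair"))
  j <- match(gene_id, scores$gene_ids)
  if (is.na(j)) stop("unknown gene id: ", gene_id)
  x <- scores$divergence[j, ]
  y <- scores$delta[j, ]
  n <- length(x)
  if (n < 3L) stop("gene ", gene_id, " has fewer than 3 samples")
  sxx <- sum((x - mean(x))^2)
  if (sxx < 1e-12) {
    return(structure(list(gene_id = gene_id, slope = NA_real_,
                          intercept = mean(y), residual_sd = NA_real_,
                          n_points = n, degenerate = TRUE),
                     class = "gene_regression_fit"))
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  structure(list(gene_id = gene_id, slope = slope, intercept = intercept,
                 residual_sd = sqrt(max(rss, 0) / (n - 2L)),
                 n_points = n, degenerate = FALSE),
            class = "gene_regression_fit")
}

#' Influence diagnostics of the per-gene regressions
#'
#' Fits, per gene, the straight line of delta count on divergence score
#' across samples and computes four influence/leverage features per
#' (gene, sample) observation:
#'
#' * `typeerror` — internally studentized residual
#'   `e_i / (s * sqrt(1 - h_ii))`;
#' * `dfbetas` — max over intercept and slope of the absolute standardized
#'   change in the coefficient when the observation is deleted;
#' * `hat` — leverage, the diagonal of the projection matrix of the design
#'   `(1, D)`; per gene the leverages sum to 2;
#' * `cooksD` — Cook's distance
#'   `(typeerror^2 / 2) * h_ii / (1 - h_ii)`.
#'
#' All four are computed in closed form, vectorized across genes (every
#' gene shares the same sample count), and agree with an explicit
#' leave-one-out refit. Genes with fewer than `min_points` samples or a
#' degenerate (constant) predictor are excluded and reported via the
#' `excluded` attribute. Observations at an exact leverage point
#' (`h_ii = 1`) receive infinite `typeerror`/`cooksD` as an
#' infinite-influence sentinel.
#'
#' @param scores A `score_pair`.
#' @param min_points Minimum samples per gene (default 3).
#' @return A data.frame of class `diagnostics_table` with columns
#'   `gene_id`, `sample_id`, `typeerror`, `dfbetas`, `hat`, `cooksD`;
#'   attributes `fits` (per-gene slope/intercept/residual_sd) and
#'   `excluded` (gene, reason).
#' @export
regression_diagnostics <- function(scores, min_points = 3L) {
  stopifnot(inherits(scores, "score_pair"))
  X <- scores$divergence
  Y <- scores$delta
  ng <- nrow(X); n <- ncol(X)
  excluded <- data.frame(gene_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (n < min_points) {
    excluded <- data.frame(gene_id = scores$gene_ids,
                           reason = "fewer than min_points samples",
                           stringsAsFactors = FALSE)
    out <- empty_diagnostics()
    attr(out, "excluded") <- excluded
    return(out)
  }

  xbar <- rowMeans(X)
  xc <- X - xbar
  sxx <- rowSums(xc^2)
  degen <- sxx < 1e-12
  ybar <- rowMeans(Y)
  slope <- ifelse(degen, NA_real_, rowSums(xc * (Y - ybar)) / sxx)
  intercept <- ybar - slope * xbar
  E <- Y - intercept - slope * X            # residuals
  rss <- rowSums(E^2)
  s2 <- pmax(rss, 0) / (n - 2L)
  s <- sqrt(s2)

  H <- 1 / n + xc^2 / sxx                   # leverages
  at_lev <- H > 1 - 1e-10
  one_m_h <- pmax(1 - H, .Machine$double.eps)
  Tstd <- E / (s * sqrt(one_m_h))           # studentized residual
  Tstd[s == 0] <- 0                         # perfect fit: no influence
  Tstd[at_lev] <- Inf
  CookD <- (Tstd^2 / 2) * (H / one_m_h)
  CookD[at_lev] <- Inf

  # standardized DFBETAS in closed form; (X'X)^{-1} entries per gene
  sumx2 <- sxx + n * xbar^2
  inv11 <- sumx2 / (n * sxx)                # intercept variance factor
  inv22 <- 1 / sxx                          # slope variance factor
  inv12 <- -xbar / sxx
  e_over <- E / one_m_h
  dbeta0 <- (inv11 + inv12 * X) * e_over    # raw dfbeta, intercept
  dbeta1 <- (inv12 + inv22 * X) * e_over    # raw dfbeta, slope
  s2i <- ((n - 2L) * s2 - E^2 / one_m_h) / (n - 3L)   # sigma^2 without obs i
  si <- sqrt(pmax(s2i, 0))
  dfb0 <- abs(dbeta0) / (si * sqrt(inv11))
  dfb1 <- abs(dbeta1) / (si * sqrt(inv22))
  DFB <- pmax(dfb0, dfb1)
  DFB[s == 0] <- 0

  keep <- !degen
  if (any(degen))
    excluded <- rbind(excluded,
                      data.frame(gene_id = scores$gene_ids[degen],
                                 reason = "degenerate predictor (constant divergence score)",
                                 stringsAsFactors = FALSE))

  idx <- which(keep)
  out <- data.frame(
    gene_id = rep(scores$gene_ids[idx], times = n),
    sample_id = rep(scores$sample_ids, each = length(idx)),
    typeerror = as.vector(Tstd[idx, ]),
    dfbetas = as.vector(DFB[idx, ]),
    hat = as.vector(H[idx, ]),
    cooksD = as.vector(CookD[idx, ]),
    stringsAsFactors = FALSE)
  class(out) <- c("diagnostics_table", "data.frame")
  attr(out, "fits") <- data.frame(
    gene_id = scores$gene_ids, slope = slope, intercept = intercept,
    residual_sd = ifelse(degen, NA_real_, s), n_points = n,
    degenerate = degen, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

empty_diagnostics <- function() {
  out <- data.frame(gene_id = character(0), sample_id = character(0),
                    typeerror = numeric(0), dfbetas = numeric(0),
                    hat = numeric(0), cooksD = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("diagnostics_table", "data.frame")
  out
}
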