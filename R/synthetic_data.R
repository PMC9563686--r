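#' Specify a synthetic RNA-seq cohort
#'
#' Parameters of a negative-binomial cohort generator emulating a bulk
#' RNA-seq compendium: per-gene mean expression drawn log-normally,
#' per-sample sequencing-depth size factors, an NB dispersion shared or per
#' gene, and optional categorical covariates that shift a fraction of genes
#' by a fixed log2 effect (sex- or batch-like structure).
#'
#' Defaults sketch a deeply sequenced bulk cohort: median gene mean
#' `exp(3) ~ 20` counts with a wide log-normal spread (`sd_log_mu = 1.5`),
#' dispersion 0.1 (NB variance `mu + 0.1 mu^2`), and 0.3 log-sd depth
#' variation between samples.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param mean_log_mu,sd_log_mu Natural-log mean and sd of the per-gene
#'   mean expression distribution.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2);
#'   scalar or one value per gene.
#' @param size_factor_sd Log-scale sd of the per-sample size factors
#'   (0 = equal depth).
#' @param covariate_effects Optional list of covariates, each a list with
#'   elements `name`, `levels` (character), `fraction` of genes affected and
#'   `log2fc` applied to non-reference levels.
#' @param seed Integer seed; equal seeds give identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, n_genes, mean_log_mu = 3, sd_log_mu = 1.5,
                        dispersion = 0.1, size_factor_sd = 0.3,
                        covariate_effects = NULL, seed = 1L) {
  stopifnot(n_samples >= 1, n_genes >= 1, all(dispersion > 0),
            sd_log_mu >= 0, size_factor_sd >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 mean_log_mu = mean_log_mu, sd_log_mu = sd_log_mu,
                 dispersion = dispersion, size_factor_sd = size_factor_sd,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic negative-binomial cohort
#'
#' Draws counts `k_ij ~ NB(mean = s_i * mu_j * c_ij, dispersion)` where
#' `s_i` are per-sample size factors, `mu_j` log-normal gene means and
#' `c_ij` the covariate multiplier for sample i at gene j. Deterministic
#' given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `counts`
#'   (genes x samples matrix), `covariates` (data.frame, possibly only
#'   `sample_id`), `size_factors` (true factors, geometric mean 1) and
#'   `gene_means`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ns <- spec$n_samples; ng <- spec$n_genes
  gene_ids <- sprintf("gene_%05d", seq_len(ng))
  sample_ids <- sprintf("sample_%04d", seq_len(ns))

  mu <- stats::rlnorm(ng, meanlog = spec$mean_log_mu, sdlog = spec$sd_log_mu)
  if (spec$size_factor_sd > 0) {
    sf <- stats::rlnorm(ns, 0, spec$size_factor_sd)
    sf <- sf / exp(mean(log(sf)))
  } else sf <- rep(1, ns)
  names(sf) <- sample_ids

  covdf <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  logfc <- matrix(0, ng, ns)   # log2 covariate effect per (gene, sample)
  for (cv in spec$covariate_effects) {
    lv <- cv$levels
    assign_lv <- sample(lv, ns, replace = TRUE)
    covdf[[cv$name]] <- factor(assign_lv, levels = lv)
    hit <- sample.int(ng, max(0L, round(cv$fraction * ng)))
    eff <- ifelse(assign_lv == lv[1L], 0, cv$log2fc)
    logfc[hit, ] <- logfc[hit, ] + matrix(eff, length(hit), ns, byrow = TRUE)
  }

  mean_mat <- outer(mu, sf) * 2^logfc
  size <- 1 / spec$dispersion   # NB size parameter, recycled per gene
  counts <- matrix(stats::rnbinom(ng * ns, mu = mean_mat, size = size),
                   ng, ns, dimnames = list(gene_ids, sample_ids))
  storage.mode(counts) <- "double"
  structure(list(counts = counts, covariates = covdf, size_factors = sf,
                 gene_means = stats::setNames(mu, gene_ids), spec = spec),
            class = "synthetic_cohort")
}

#' Parameters of the aberration-injection model
#'
#' Per-entry Bernoulli corruption of a count matrix. Each selected entry is
#' replaced by `round(s_i * 2^(mu_j^u +/- exp(N) * sigma_j^u))` where
#' `mu_j^u` and `sigma_j^u` are the mean and sd of the gene's log2
#' size-factor-normalized profile `u = log2(k/s + 1)` and the aberration
#' amplitude `exp(N)` is log-normal, `N ~ Normal(meanlog, sdlog)`. Defaults
#' give a median amplitude of 3 z-score units (`meanlog = log 3`,
#' `sdlog = log 1.6`).
#'
#' @param probability Per-entry injection probability in `[0, 1]`.
#' @param amplitude_meanlog Mean of `N` (default `log(3)`).
#' @param amplitude_sdlog Sd of `N` (default `log(1.6)`), must be > 0.
#' @param seed Integer seed.
#' @return An object of class `injection_params`.
#' @export
injection_params <- function(probability, amplitude_meanlog = log(3),
                             amplitude_sdlog = log(1.6), seed = 1L) {
  stopifnot(probability >= 0, probability <= 1, amplitude_sdlog > 0)
  structure(list(probability = probability,
                 amplitude_meanlog = amplitude_meanlog,
                 amplitude_sdlog = amplitude_sdlog,
                 seed = as.integer(seed)),
            class = "injection_params")
}

#' Draw aberration amplitudes
#'
#' The multiplicative z-score amplitude `exp(N)` of the injection model;
#' exposed so its log-normal calibration can be checked directly.
#'
#' @param n Number of draws.
#' @param params An [injection_params()].
#' @return Numeric vector of positive amplitudes.
#' @export
draw_amplitudes <- function(n, params = injection_params(0)) {
  exp(stats::rnorm(n, params$amplitude_meanlog, params$amplitude_sdlog))
}

#' Inject artificial aberrant expression into a count matrix
#'
#' Semi-synthetic corruption: every (gene, sample) entry is independently
#' selected with `params$probability`; selected entries are replaced by an
#' up- or down-shifted count (sign chosen with probability 1/2 each) of
#' `round(s_i * 2^(mu_j^u +/- exp(N) * sigma_j^u))`, clipped below at 0 and
#' rounded half-away-from-zero. Entries in genes whose profile sd is zero
#' cannot be displaced and are left untouched (and excluded from the mask).
#'
#' @param m Count matrix (genes x samples).
#' @param params An [injection_params()].
#' @param sf Size factors aligned to `m`'s samples; estimated via
#'   [estimate_size_factors()] when `NULL`.
#' @return A `labeled_dataset`: list with `corrupted` and `original` count
#'   matrices, logical `mask` (TRUE = injected), integer `direction`
#'   (+1 up, -1 down, 0 untouched), `size_factors`, `params`, and attributes
#'   `n_zero_sd_skipped` and `collapsed_fraction` (injections where rounding
#'   returned the original value).
#' @export
inject_aberrations <- function(m, params, sf = NULL) {
  validate_counts(m)
  stopifnot(inherits(params, "injection_params"))
  if (is.null(sf)) sf <- estimate_size_factors(m)
  if (!identical(names(sf), colnames(m)))
    stop("size factors are not aligned to the sample ids of the matrix")
  ng <- nrow(m); ns <- ncol(m)

  set.seed(params$seed)
  sel <- which(matrix(stats::runif(ng * ns) < params$probability, ng, ns))
  u <- log2(sweep(m, 2L, sf, "/") + 1)
  mu_u <- rowMeans(u)
  sd_u <- row_sds(u)             # sample sd across the cohort

  mask <- matrix(FALSE, ng, ns, dimnames = dimnames(m))
  direction <- matrix(0L, ng, ns, dimnames = dimnames(m))
  corrupted <- m
  n_zero_sd <- 0L
  if (length(sel)) {
    gi <- ((sel - 1L) %% ng) + 1L
    si <- ((sel - 1L) %/% ng) + 1L
    amp <- exp(stats::rnorm(length(sel), params$amplitude_meanlog,
                            params$amplitude_sdlog))
    sgn <- sample(c(1, -1), length(sel), replace = TRUE)
    usable <- sd_u[gi] > 0
    n_zero_sd <- sum(!usable)
    if (n_zero_sd)
      message(n_zero_sd, " injection(s) skipped: gene profile sd is zero")
    gi <- gi[usable]; si <- si[usable]
    amp <- amp[usable]; sgn <- sgn[usable]; sel <- sel[usable]
    newval <- sf[si] * 2^(mu_u[gi] + sgn * amp * sd_u[gi])
    corrupted[sel] <- floor(pmax(newval, 0) + 0.5)  # half-away-from-zero
    mask[sel] <- TRUE
    direction[sel] <- as.integer(sgn)
  }
  structure(list(corrupted = corrupted, mask = mask, direction = direction,
                 original = m, size_factors = sf, params = params),
            class = "labeled_dataset",
            n_zero_sd_skipped = n_zero_sd,
            collapsed_fraction = if (length(sel))
                mean(corrupted[sel] == m[sel]) else 0)
}

#' Build the semi-synthetic benchmark grid
#'
#' One corrupted dataset per (cohort size, injection probability) pair. The
#' base cohort is generated once (or supplied as a matrix) and each dataset
#' takes a random subset of its samples before injection, so the grid
#' mimics repeatedly sampling a large compendium.
#'
#' @param base A [cohort_spec()] (its `n_samples` must reach `max(sizes)`),
#'   a `synthetic_cohort`, or a plain count matrix.
#' @param sizes Integer vector of cohort sizes, default the benchmark's
#'   `c(50, 75, 125, 250, 500, 1000)`.
#' @param probabilities Injection probabilities, default
#'   `c(1e-6, 1e-5, 1e-4)`.
#' @param params Amplitude settings used for every dataset (its
#'   `probability`/`seed` fields are overridden per dataset).
#' @param seed Grid-level seed from which per-dataset seeds are derived.
#' @return List of `labeled_dataset` objects, one per (size, probability)
#'   pair, each carrying a `provenance` attribute (size, probability, seed).
#' @export
build_benchmark_grid <- function(base,
                                 sizes = c(50, 75, 125, 250, 500, 1000),
                                 probabilities = c(1e-6, 1e-5, 1e-4),
                                 params = injection_params(0),
                                 seed = 1L) {
  stopifnot(length(sizes) > 0, length(probabilities) > 0)
  if (inherits(base, "cohort_spec")) {
    if (base$n_samples < max(sizes))
      stop("base cohort has ", base$n_samples,
           " samples but the grid requests ", max(sizes))
    base <- generate_cohort(base)
  }
  counts <- if (inherits(base, "synthetic_cohort")) base$counts else base
  validate_counts(counts)
  if (ncol(counts) < max(sizes))
    stop("base cohort has ", ncol(counts),
         " samples but the grid requests ", max(sizes))

  out <- vector("list", length(sizes) * length(probabilities))
  k <- 0L
  for (sz in sizes) {
    for (p in probabilities) {
      k <- k + 1L
      ds_seed <- as.integer((seed + 7919L * k) %% .Machine$integer.max)
      set.seed(ds_seed)
      cols <- sort(sample.int(ncol(counts), sz))
      sub <- counts[, cols, drop = FALSE]
      sfs <- estimate_size_factors(sub)
      ip <- injection_params(p, params$amplitude_meanlog,
                             params$amplitude_sdlog, seed = ds_seed + 1L)
      ds <- inject_aberrations(sub, ip, sfs)
      attr(ds, "provenance") <- list(size = sz, probability = p,
                                     seed = ds_seed)
      out[[k]] <- ds
    }
  }
  out
}

#' Subsample a cohort into nested small datasets
#'
#' For each requested size, draws `replicates` datasets that always contain
#' the `keep_samples` (e.g. patients with validated aberrations) plus a
#' fresh random complement from the remaining samples, without replacement.
#' Used to probe how detection degrades as the cohort shrinks.
#'
#' @param m Count matrix.
#' @param keep_samples Sample ids every dataset must contain.
#' @param sizes Dataset sizes; each must be at least `length(keep_samples)`.
#' @param replicates Datasets per size (default 10).
#' @param seed Integer seed.
#' @return List of count matrices of length `length(sizes) * replicates`,
#'   each with a `provenance` attribute (size, replicate).
#' @export
subsample_small_datasets <- function(m, keep_samples, sizes, replicates = 10,
                                     seed = 1L) {
  validate_counts(m)
  if (!all(keep_samples %in% colnames(m)))
    stop("keep_samples not all present in the matrix: ",
         paste(setdiff(keep_samples, colnames(m)), collapse = ", "))
  if (any(sizes < length(keep_samples)))
    stop("every size must be >= the number of kept samples (",
         length(keep_samples), ")")
  rest <- setdiff(colnames(m), keep_samples)
  set.seed(seed)
  out <- list()
  for (sz in sizes) {
    for (r in seq_len(replicates)) {
      extra <- sample(rest, sz - length(keep_samples))
      cols <- c(keep_samples, extra)
      ds <- m[, cols, drop = FALSE]
      attr(ds, "provenance") <- list(size = sz, replicate = r)
      out[[length(out) + 1L]] <- ds
    }
  }
  out
}

# sample sd of each row (denominator n - 1); 0 for constant rows
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(0, nrow(x)))
  mu <- rowMeans(x)
  sqrt(pmax(rowSums((x - mu)^2) / (n - 1L), 0))
}

# population sd of each row (denominator n)
row_sds_pop <- function(x) {
  mu <- rowMeans(x)
  sqrt(pmax(rowMeans((x - mu)^2), 0))
}
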