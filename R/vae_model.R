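#' Configuration of the variational autoencoder
#'
#' The model compresses each sample's expression profile through four dense
#' hidden layers (each dense -> batch normalization -> ELU) into a
#' 128-dimensional Gaussian latent space and mirrors the architecture back
#' out. Training maximizes the usual evidence lower bound: a Gaussian
#' (mean-squared-error) reconstruction term on the preprocessed feature
#' scale plus `kl_weight` times the KL divergence of the latent posterior
#' from a standard normal, with reparameterized sampling.
#'
#' `hidden_sizes = NULL` picks a geometric taper from the gene count down to
#' the latent width, capped at 1024 units per layer.
#'
#' @param latent_dim Latent width (default 128).
#' @param n_hidden_layers Hidden layers per side (default 4).
#' @param hidden_sizes Explicit encoder layer widths (decoder mirrors them);
#'   `NULL` for the automatic taper.
#' @param batch_norm Insert batch normalization after every hidden dense
#'   layer (default TRUE).
#' @param epochs,batch_size,learning_rate Training hyperparameters.
#' @param kl_weight Weight of the KL term (default 1, the plain ELBO).
#' @param early_stop_patience Stop when the epoch training loss has not
#'   improved for this many epochs (default 30).
#' @param seed Integer seed governing initialization, shuffling and the
#'   latent sampling noise.
#' @return An object of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 128L, n_hidden_layers = 4L,
                       hidden_sizes = NULL, batch_norm = TRUE,
                       epochs = 300L, batch_size = 32L,
                       learning_rate = 1e-3, kl_weight = 1,
                       early_stop_patience = 30L, seed = 1L) {
  stopifnot(latent_dim >= 1, n_hidden_layers >= 1, epochs >= 0,
            batch_size >= 1, learning_rate > 0, kl_weight >= 0)
  if (!is.null(hidden_sizes)) {
    if (length(hidden_sizes) != n_hidden_layers)
      stop("hidden_sizes must have n_hidden_layers entries")
    if (any(hidden_sizes < 1)) stop("hidden sizes must be positive")
  }
  structure(list(latent_dim = as.integer(latent_dim),
                 n_hidden_layers = as.integer(n_hidden_layers),
                 hidden_sizes = if (is.null(hidden_sizes)) NULL
                                else as.integer(hidden_sizes),
                 batch_norm = isTRUE(batch_norm),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, kl_weight = kl_weight,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "vae_config")
}

default_hidden_sizes <- function(cfg, n_genes) {
  if (!is.null(cfg$hidden_sizes)) return(cfg$hidden_sizes)
  s <- exp(seq(log(max(n_genes, cfg$latent_dim + 1)), log(cfg$latent_dim),
               length.out = cfg$n_hidden_layers + 2L))
  pmin(as.integer(round(s[-c(1L, length(s))])), 1024L)
}

#' Preprocess counts into the model's feature representation
#'
#' Per-gene standardized `log2(k/s + 1)`: counts are depth-normalized by the
#' size factors, log2-transformed with a pseudocount, then centered and
#' scaled gene-wise. Zero-variance genes get scale 1 so they map to an
#' all-zero column. The stored transform parameters invert the map exactly,
#' which is what puts reconstructions back on the count scale.
#'
#' @param m Count matrix (genes x samples).
#' @param sf Size factors aligned to `m`.
#' @return A `feature_matrix`: list with `values` (samples x genes),
#'   `gene_means`, `gene_sds`, `size_factors`, `gene_ids`, `sample_ids` and
#'   `n_zero_variance`.
#' @export
preprocess_counts <- function(m, sf) {
  validate_counts(m)
  if (!identical(names(sf), colnames(m)))
    stop("size factors are not aligned to the sample ids of the matrix")
  u <- log2(sweep(m, 2L, sf, "/") + 1)
  mu <- rowMeans(u)
  sd <- row_sds(u)
  zero <- sd == 0
  sd[zero] <- 1
  vals <- t((u - mu) / sd)    # samples x genes
  structure(list(values = vals, gene_means = mu, gene_sds = sd,
                 size_factors = sf, gene_ids = rownames(m),
                 sample_ids = colnames(m), n_zero_variance = sum(zero)),
            class = "feature_matrix")
}

#' Invert the preprocessing transform
#'
#' Maps feature-scale values back to the `log2(k/s + 1)` scale (and, with
#' `to_counts = TRUE`, all the way to non-negative counts
#' `s * (2^u - 1)` clipped at 0).
#'
#' @param f The `feature_matrix` holding the transform parameters.
#' @param values Samples x genes feature-scale matrix (default the stored
#'   values).
#' @param to_counts Return counts instead of the log2 scale.
#' @return Genes x samples matrix.
#' @export
inverse_preprocess <- function(f, values = f$values, to_counts = FALSE) {
  u <- t(values) * f$gene_sds + f$gene_means   # genes x samples
  if (!to_counts) return(u)
  k <- sweep(2^u - 1, 2L, f$size_factors, "*")
  pmax(k, 0)
}

#' Build an untrained variational autoencoder
#'
#' @param cfg A [vae_config()].
#' @param n_genes Input (and output) width.
#' @return An object of class `vae_model` holding encoder, latent heads and
#'   decoder layer stacks.
#' @export
build_vae <- function(cfg, n_genes) {
  stopifnot(inherits(cfg, "vae_config"), n_genes >= 1)
  sizes <- default_hidden_sizes(cfg, n_genes)
  if (!length(sizes)) stop("empty hidden layer specification")
  set.seed(cfg$seed)
  mk_block <- function(n_in, n_out) {
    b <- list(layer_dense(n_in, n_out))
    if (cfg$batch_norm) b <- c(b, list(layer_batchnorm(n_out)))
    c(b, list(layer_elu()))
  }
  enc <- list(); n_in <- n_genes
  for (s in sizes) { enc <- c(enc, mk_block(n_in, s)); n_in <- s }
  mu_head <- list(layer_dense(n_in, cfg$latent_dim))
  lv_head <- list(layer_dense(n_in, cfg$latent_dim))
  dec <- list(); n_in <- cfg$latent_dim
  for (s in rev(sizes)) { dec <- c(dec, mk_block(n_in, s)); n_in <- s }
  dec <- c(dec, list(layer_dense(n_in, n_genes)))
  structure(list(encoder = enc, mu_head = mu_head, lv_head = lv_head,
                 decoder = dec, cfg = cfg, n_genes = as.integer(n_genes),
                 hidden_sizes = sizes, gene_ids = NULL, trained = FALSE,
                 history = numeric(0)),
            class = "vae_model")
}

#' Number of trainable parameters of a VAE
#'
#' @param model A `vae_model`.
#' @return Integer parameter count (weights, biases, batch-norm scale/shift).
#' @export
vae_n_params <- function(model) {
  as.integer(layers_n_params(model$encoder) +
             layers_n_params(model$mu_head) +
             layers_n_params(model$lv_head) +
             layers_n_params(model$decoder))
}

# Closed-form KL(q || N(0, I)) per sample, summed over latent dimensions
kl_divergence <- function(mu, logvar) {
  0.5 * rowSums(exp(logvar) + mu^2 - 1 - logvar)
}

#' Train a variational autoencoder
#'
#' Minibatch Adam on the negative ELBO: mean over the batch of the
#' per-sample squared reconstruction error plus `kl_weight` times the KL
#' term. Deterministic given the config seed (initialization, shuffling and
#' sampling noise all flow from it). Training stops early once the epoch
#' loss has not improved for `early_stop_patience` epochs.
#'
#' @param model An untrained (or previously trained) `vae_model`.
#' @param f A `feature_matrix` from [preprocess_counts()].
#' @param cfg Optional config override (defaults to the model's).
#' @return The trained model; `$history` holds the per-epoch mean loss.
#' @export
train_vae <- function(model, f, cfg = model$cfg) {
  stopifnot(inherits(model, "vae_model"), inherits(f, "feature_matrix"))
  x_all <- f$values
  if (ncol(x_all) != model$n_genes)
    stop("feature matrix has ", ncol(x_all), " genes; model expects ",
         model$n_genes)
  n <- nrow(x_all)
  if (n < 1L) stop("empty feature matrix")
  model$gene_ids <- f$gene_ids
  if (cfg$epochs == 0L) { model$history <- numeric(0); return(model) }

  set.seed(cfg$seed + 1L)
  st <- list(enc = layers_adam_init(model$encoder),
             mu = layers_adam_init(model$mu_head),
             lv = layers_adam_init(model$lv_head),
             dec = layers_adam_init(model$decoder))
  lr <- cfg$learning_rate; klw <- cfg$kl_weight
  history <- numeric(0); best <- Inf; best_epoch <- 0L; t_step <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (idx in batches) {
      x <- x_all[idx, , drop = FALSE]
      nb <- nrow(x)
      fe <- stack_forward(model$encoder, x, training = TRUE)
      fmu <- stack_forward(model$mu_head, fe$out, training = TRUE)
      flv <- stack_forward(model$lv_head, fe$out, training = TRUE)
      mu <- fmu$out
      lv <- pmin(pmax(flv$out, -15), 15)   # keep exp() sane early on
      epsn <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
      z <- mu + exp(0.5 * lv) * epsn
      fd <- stack_forward(model$decoder, z, training = TRUE)
      xhat <- fd$out

      rec <- sum((xhat - x)^2) / nb
      kl <- sum(kl_divergence(mu, lv)) / nb
      loss <- rec + klw * kl
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch,
             "; try a smaller learning rate")
      ep_loss <- ep_loss + loss * nb / n

      dxhat <- 2 * (xhat - x) / nb
      bd <- stack_backward(model$decoder, dxhat, fd$caches)
      dz <- bd$dx
      dmu <- dz + klw * mu / nb
      dlv <- dz * epsn * 0.5 * exp(0.5 * lv) +
             klw * 0.5 * (exp(lv) - 1) / nb
      bmu <- stack_backward(model$mu_head, dmu, fmu$caches)
      blv <- stack_backward(model$lv_head, dlv, flv$caches)
      be <- stack_backward(model$encoder, bmu$dx + blv$dx, fe$caches)

      t_step <- t_step + 1L
      up <- layers_adam_update(model$decoder, bd$grads, st$dec, lr, t_step)
      model$decoder <- up$layers; st$dec <- up$states
      up <- layers_adam_update(model$mu_head, bmu$grads, st$mu, lr, t_step)
      model$mu_head <- up$layers; st$mu <- up$states
      up <- layers_adam_update(model$lv_head, blv$grads, st$lv, lr, t_step)
      model$lv_head <- up$layers; st$lv <- up$states
      up <- layers_adam_update(model$encoder, be$grads, st$enc, lr, t_step)
      model$encoder <- up$layers; st$enc <- up$states

      # refresh batch-norm running statistics
      for (i in seq_along(model$encoder))
        model$encoder[[i]] <- layer_update_running(model$encoder[[i]],
                                                   fe$caches[[i]])
      for (i in seq_along(model$decoder))
        model$decoder[[i]] <- layer_update_running(model$decoder[[i]],
                                                   fd$caches[[i]])
    }
    history <- c(history, ep_loss)
    if (ep_loss < best - 1e-8) { best <- ep_loss; best_epoch <- epoch }
    if (epoch - best_epoch >= cfg$early_stop_patience) break
  }
  model$history <- history
  model$trained <- TRUE
  model
}

# Encoder posterior means, inference mode (running batch-norm statistics)
vae_encode_mu <- function(model, values) {
  h <- stack_forward(model$encoder, values, training = FALSE)$out
  stack_forward(model$mu_head, h, training = FALSE)$out
}

check_gene_set <- function(model, f) {
  if (!is.null(model$gene_ids) && !identical(model$gene_ids, f$gene_ids)) {
    missing <- setdiff(model$gene_ids, f$gene_ids)
    stop("gene set mismatch between model and features",
         if (length(missing)) paste0("; missing: ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (length(missing) > 5L) ", ..."))
  }
  if (ncol(f$values) != model$n_genes)
    stop("feature matrix has ", ncol(f$values), " genes; model expects ",
         model$n_genes)
}

#' Reconstruct counts through the trained autoencoder
#'
#' Deterministic reconstruction: the sample is encoded to its posterior
#' mean (no sampling), decoded in inference mode, and the preprocessing
#' transform is inverted back to the count scale
#' (`k_hat = s * (2^u - 1)`, clipped at 0).
#'
#' @param model A `vae_model`.
#' @param f A `feature_matrix` over the model's gene set.
#' @return Genes x samples matrix of non-negative reconstructed counts.
#' @export
reconstruct_counts <- function(model, f) {
  stopifnot(inherits(model, "vae_model"), inherits(f, "feature_matrix"))
  check_gene_set(model, f)
  mu <- vae_encode_mu(model, f$values)
  xhat <- stack_forward(model$decoder, mu, training = FALSE)$out
  khat <- inverse_preprocess(f, xhat, to_counts = TRUE)
  dimnames(khat) <- list(f$gene_ids, f$sample_ids)
  khat
}

#' Extract the latent representation of each sample
#'
#' Posterior means of the latent code, so repeated calls agree bit-wise.
#' The per-sample coordinates can be joined with covariates to inspect what
#' the compressed dimensions encode (sex, batch, ...).
#'
#' @param model A `vae_model`.
#' @param f A `feature_matrix` over the model's gene set.
#' @return Samples x `latent_dim` matrix with sample ids as rownames.
#' @export
encode_latent <- function(model, f) {
  stopifnot(inherits(model, "vae_model"), inherits(f, "feature_matrix"))
  check_gene_set(model, f)
  z <- vae_encode_mu(model, f$values)
  rownames(z) <- f$sample_ids
  colnames(z) <- sprintf("latent_%03d", seq_len(ncol(z)))
  z
}

#' Associate latent dimensions with sample covariates
#'
#' For every (latent dimension, covariate) pair, fits a one-way linear model
#' of the latent coordinate on the categorical covariate and reports the
#' R-squared (for two-level covariates, the squared point-biserial
#' correlation).
#'
#' @param latent Samples x dims matrix from [encode_latent()].
#' @param covariates Data.frame with `sample_id` plus categorical columns.
#' @return Data.frame (dimension, covariate, r_squared) sorted by
#'   descending association.
#' @export
latent_covariate_association <- function(latent, covariates) {
  stopifnot(is.matrix(latent), "sample_id" %in% names(covariates))
  cv <- covariates[match(rownames(latent), covariates$sample_id), ,
                   drop = FALSE]
  vars <- setdiff(names(cv), "sample_id")
  out <- expand.grid(dimension = colnames(latent), covariate = vars,
                     stringsAsFactors = FALSE)
  if (nrow(out) == 0L) {
    out$r_squared <- numeric(0)
    return(out)
  }
  out$r_squared <- mapply(function(d, v) {
    g <- cv[[v]]
    if (length(unique(g[!is.na(g)])) < 2L) return(NA_real_)
    summary(stats::lm(latent[, d] ~ g))$r.squared
  }, out$dimension, out$covariate)
  out[order(-out$r_squared), ]
}

#' @export
print.vae_model <- function(x, ...) {
  cat("Variational autoencoder\n")
  cat("  input genes: ", x$n_genes, "\n", sep = "")
  cat("  encoder widths: ", paste(x$hidden_sizes, collapse = " -> "),
      " -> latent ", x$cfg$latent_dim, "\n", sep = "")
  cat("  parameters: ", vae_n_params(x), "\n", sep = "")
  cat("  trained: ", x$trained,
      if (length(x$history)) paste0(" (", length(x$history),
        " epochs, final loss ", signif(utils::tail(x$history, 1), 4), ")"),
      "\n", sep = "")
  invisible(x)
}
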