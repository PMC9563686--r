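# Shared fixtures, all generated in code.

# small random count matrix with dimnames
rand_counts <- function(ng, ns, lambda = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(ng * ns, lambda), ng, ns,
              dimnames = list(sprintf("g%03d", seq_len(ng)),
                              sprintf("s%03d", seq_len(ns))))
  storage.mode(m) <- "double"
  m
}

# score_pair built directly from given divergence/delta matrices
make_score_pair <- function(D, Delta) {
  gene_ids <- sprintf("g%03d", seq_len(nrow(D)))
  sample_ids <- sprintf("s%03d", seq_len(ncol(D)))
  dimnames(D) <- dimnames(Delta) <- list(gene_ids, sample_ids)
  structure(list(divergence = D, delta = Delta, ratio = D * 0 + 1,
                 gene_count_means = rep(1, nrow(D)),
                 ratio_center = rep(0, nrow(D)),
                 ratio_scale = rep(1, nrow(D)),
                 axis = "per_gene", gene_ids = gene_ids,
                 sample_ids = sample_ids),
            class = "score_pair")
}

# a tiny trained detector shared by pipeline-level tests (built once)
tiny_cfg <- function(seed = 1, epochs = 60) {
  agescan_config(vae = vae_config(latent_dim = 8,
                                  hidden_sizes = c(64, 32, 24, 16),
                                  epochs = epochs, seed = 1),
                 seed = seed)
}

tiny_labeled <- function(seed = 7, n_samples = 40, n_genes = 400,
                         p = 2e-3) {
  cohort <- generate_cohort(cohort_spec(n_samples, n_genes, seed = seed))
  inj <- inject_aberrations(cohort$counts,
                            injection_params(p, seed = seed + 1),
                            cohort$size_factors)
  inj
}
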