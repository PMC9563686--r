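test_that("preprocessing standardizes per gene, guards zero variance, and inverts exactly", {
  m <- rand_counts(80, 12, lambda = 25, seed = 1)
  m[5, ] <- 10   # constant normalized profile at unit size factors
  sf <- setNames(rep(1, 12), colnames(m))
  f <- preprocess_counts(m, sf)
  expect_identical(dim(f$values), c(12L, 80L))
  expect_equal(unname(f$values[, 5]), rep(0, 12))   # zero-variance column
  expect_identical(f$n_zero_variance, 1L)

  u <- log2(sweep(m, 2, sf, "/") + 1)
  expect_lt(max(abs(inverse_preprocess(f) - u)), 1e-9)
  k <- inverse_preprocess(f, to_counts = TRUE)
  expect_lt(max(abs(k - m)), 1e-6)

  # direct formula at unit size factors
  m2 <- rand_counts(3, 5, lambda = 5, seed = 2)
  m2[1, ] <- c(3, 0, 1, 8, 2)
  sf1 <- setNames(rep(1, 5), colnames(m2))
  f2 <- preprocess_counts(m2, sf1)
  g <- log2(m2[1, ] + 1)
  expect_equal(unname(f2$values[1, 1]),
               unname((log2(4) - mean(g)) / sd(g)))
})

test_that("architecture contract: latent width, parameter count, KL closed form", {
  cfg <- vae_config(latent_dim = 7, hidden_sizes = c(20, 10, 9, 8),
                    seed = 1)
  model <- build_vae(cfg, 50)
  f <- preprocess_counts(rand_counts(50, 6, seed = 3),
                         setNames(rep(1, 6), sprintf("s%03d", 1:6)))
  z <- encode_latent(model, f)
  expect_identical(dim(z), c(6L, 7L))

  # symbolic parameter count: dense W+b plus batchnorm gamma+beta per block
  sizes <- c(50, 20, 10, 9, 8)
  enc <- sum(sizes[-5] * sizes[-1] + sizes[-1]) + sum(2 * sizes[-1])
  heads <- 2 * (8 * 7 + 7)
  dsz <- c(7, 8, 9, 10, 20)
  dec <- sum(dsz[-5] * dsz[-1] + dsz[-1]) + sum(2 * dsz[-1]) +
         (20 * 50 + 50)
  expect_identical(vae_n_params(model), as.integer(enc + heads + dec))

  # KL of a standard-normal posterior is exactly zero
  expect_identical(agescan:::kl_divergence(matrix(0, 2, 4),
                                           matrix(0, 2, 4)), c(0, 0))
})

test_that("training is deterministic, reduces the loss, and 0 epochs is a no-op", {
  m <- rand_counts(200, 30, lambda = 30, seed = 4)
  f <- preprocess_counts(m, estimate_size_factors(m))
  cfg <- vae_config(latent_dim = 6, hidden_sizes = c(32, 16, 12, 8),
                    epochs = 40, seed = 9)
  t1 <- train_vae(build_vae(cfg, 200), f, cfg)
  t2 <- train_vae(build_vae(cfg, 200), f, cfg)
  expect_identical(t1$history, t2$history)
  expect_lt(tail(t1$history, 1), 0.9 * t1$history[1])

  cfg0 <- vae_config(latent_dim = 6, hidden_sizes = c(32, 16, 12, 8),
                     epochs = 0, seed = 9)
  t0 <- train_vae(build_vae(cfg0, 200), f, cfg0)
  expect_identical(t0$history, numeric(0))
  expect_false(t0$trained)
})

test_that("reconstruction is finite, non-negative, deterministic, and correlates with the input", {
  m <- rand_counts(150, 25, lambda = 40, seed = 5)
  f <- preprocess_counts(m, estimate_size_factors(m))
  cfg <- vae_config(latent_dim = 6, hidden_sizes = c(32, 16, 12, 8),
                    epochs = 60, seed = 2)
  untrained <- build_vae(cfg, 150)
  k0 <- reconstruct_counts(untrained, f)
  expect_true(all(is.finite(k0)) && all(k0 >= 0))

  model <- train_vae(untrained, f, cfg)
  k1 <- reconstruct_counts(model, f)
  expect_identical(k1, reconstruct_counts(model, f))  # posterior mean: bit-wise
  cors <- sapply(seq_len(nrow(m)), function(j)
    if (sd(m[j, ]) > 0 && sd(k1[j, ]) > 0) cor(m[j, ], k1[j, ]) else NA)
  expect_gt(median(cors, na.rm = TRUE), 0)

  f_bad <- f; f_bad$gene_ids <- rev(f$gene_ids)
  model$gene_ids <- f$gene_ids
  expect_error(reconstruct_counts(model, f_bad), "mismatch")
})

test_that("duplicate samples get identical latent rows; a strong covariate is encoded", {
  m <- rand_counts(100, 10, lambda = 30, seed = 6)
  m2 <- cbind(m, m[, 1, drop = FALSE])
  colnames(m2) <- c(colnames(m), "dup")
  sf <- setNames(rep(1, 11), colnames(m2))
  f <- preprocess_counts(m2, sf)
  cfg <- vae_config(latent_dim = 5, hidden_sizes = c(24, 12, 10, 6),
                    epochs = 20, seed = 3)
  model <- train_vae(build_vae(cfg, 100), f, cfg)
  z <- encode_latent(model, f)
  expect_equal(unname(z["dup", ]), unname(z[colnames(m)[1], ]))

  # two-group covariate shifting 20% of genes by 2x is recoverable from
  # the best latent dimension
  spec <- cohort_spec(40, 300, sd_log_mu = 1, size_factor_sd = 0.1,
                      covariate_effects = list(list(
                        name = "grp", levels = c("a", "b"),
                        fraction = 0.2, log2fc = 1)), seed = 13)
  co <- generate_cohort(spec)
  fc <- preprocess_counts(co$counts, estimate_size_factors(co$counts))
  cfg2 <- vae_config(latent_dim = 8, hidden_sizes = c(64, 32, 24, 16),
                     epochs = 80, seed = 4)
  mod2 <- train_vae(build_vae(cfg2, 300), fc, cfg2)
  z2 <- encode_latent(mod2, fc)
  grp <- as.integer(co$covariates$grp == "b")
  r <- apply(z2, 2, function(v) abs(cor(v, grp)))
  expect_gt(max(r), 0.5)

  assoc <- latent_covariate_association(z2, co$covariates)
  expect_equal(max(assoc$r_squared, na.rm = TRUE), max(r)^2,
               tolerance = 1e-9)
})

test_that("non-finite loss aborts with learning-rate advice", {
  m <- rand_counts(50, 8, seed = 7)
  f <- preprocess_counts(m, estimate_size_factors(m))
  f$values[1, 1] <- Inf   # poisoned input drives the loss non-finite
  cfg <- vae_config(latent_dim = 4, hidden_sizes = c(16, 8, 8, 6),
                    epochs = 5, seed = 1)
  expect_error(train_vae(build_vae(cfg, 50), f, cfg),
               "learning rate")
})
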