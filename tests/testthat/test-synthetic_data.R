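test_that("cohort generator: determinism, degenerate limits and NB moments", {
  spec <- cohort_spec(20, 100, seed = 5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$counts, b$counts)
  expect_identical(a$size_factors, b$size_factors)

  # flat spec: equal depth, shared gene mean; sample means near mu
  flat <- cohort_spec(500, 50, mean_log_mu = 4, sd_log_mu = 0,
                      dispersion = 1e-4, size_factor_sd = 0, seed = 2)
  fc <- generate_cohort(flat)
  mu <- exp(4)
  expect_true(all(abs(rowMeans(fc$counts) / mu - 1) < 0.1))

  # variance/mean relationship: var ~ mu + 0.1 mu^2
  spec2 <- cohort_spec(100, 2000, dispersion = 0.1, size_factor_sd = 0,
                       seed = 3)
  cc <- generate_cohort(spec2)
  gm <- rowMeans(cc$counts)
  gv <- apply(cc$counts, 1, var)
  keep <- gm > 5
  ratio <- gv[keep] / (gm[keep] + 0.1 * gm[keep]^2)
  expect_lt(abs(median(ratio) - 1), 0.2)
})

test_that("covariate effects shift the targeted fraction of genes", {
  spec <- cohort_spec(60, 500, sd_log_mu = 1, size_factor_sd = 0,
                      covariate_effects = list(list(
                        name = "sex", levels = c("F", "M"),
                        fraction = 0.2, log2fc = 1)),
                      seed = 4)
  co <- generate_cohort(spec)
  expect_true(all(c("sample_id", "sex") %in% names(co$covariates)))
  expect_identical(nrow(co$covariates), 60L)
  grp <- co$covariates$sex == "M"
  lfc <- log2((rowMeans(co$counts[, grp]) + 1) /
              (rowMeans(co$counts[, !grp]) + 1))
  # roughly 20% of genes near +1, the rest near 0
  expect_gt(sum(lfc > 0.5), 0.12 * 500)
  expect_lt(sum(lfc > 0.5), 0.30 * 500)
})

test_that("injection: no-op at p = 0, untouched entries bit-identical, directions honored", {
  m <- rand_counts(150, 25, lambda = 40, seed = 6)
  sf <- estimate_size_factors(m)
  none <- inject_aberrations(m, injection_params(0, seed = 1), sf)
  expect_identical(none$corrupted, m)
  expect_false(any(none$mask))

  ds <- inject_aberrations(m, injection_params(0.02, seed = 2), sf)
  expect_gt(sum(ds$mask), 0)
  expect_identical(ds$corrupted[!ds$mask], ds$original[!ds$mask])
  expect_true(all(ds$corrupted >= 0))
  expect_true(all(ds$corrupted == floor(ds$corrupted)))

  # up injections exceed the original, down fall below, unless collapsed
  up <- ds$mask & ds$direction > 0 & ds$corrupted != ds$original
  dn <- ds$mask & ds$direction < 0 & ds$corrupted != ds$original
  expect_true(all(ds$corrupted[up] > ds$original[up]))
  expect_true(all(ds$corrupted[dn] < ds$original[dn]))
  expect_lt(attr(ds, "collapsed_fraction"), 0.5)

  # determinism
  ds2 <- inject_aberrations(m, injection_params(0.02, seed = 2), sf)
  expect_identical(ds$corrupted, ds2$corrupted)
  expect_identical(ds$mask, ds2$mask)
})

test_that("realized injection fraction matches the Bernoulli probability", {
  m <- rand_counts(2000, 50, lambda = 30, seed = 8)
  sf <- estimate_size_factors(m)
  p <- 1e-3
  ds <- inject_aberrations(m, injection_params(p, seed = 3), sf)
  n <- length(m)
  ci <- qbinom(c(0.025, 0.975), n, p)
  expect_gte(sum(ds$mask), ci[1])
  expect_lte(sum(ds$mask), ci[2])
})

test_that("amplitude draws are log-normal with meanlog log(3) and sdlog log(1.6)", {
  set.seed(9)
  amp <- draw_amplitudes(1e5, injection_params(0))
  la <- log(amp)
  se_mean <- log(1.6) / sqrt(1e5)
  expect_lt(abs(mean(la) - log(3)), 3 * se_mean)
  se_sd <- log(1.6) / sqrt(2 * (1e5 - 1))
  expect_lt(abs(sd(la) - log(1.6)), 3 * se_sd)
})

test_that("zero-variance genes are skipped and logged by the injector", {
  m <- rand_counts(5, 10, lambda = 20, seed = 10)
  m[1, ] <- 50   # constant profile: sigma_u = 0
  sf <- setNames(rep(1, 10), colnames(m))
  expect_message(
    ds <- inject_aberrations(m, injection_params(1, seed = 4), sf),
    "sd is zero")
  expect_false(any(ds$mask[1, ]))
  expect_identical(ds$corrupted[1, ], m[1, ])
  expect_true(all(ds$mask[2:5, ]))
})

test_that("benchmark grid has one dataset per (size, probability) pair", {
  base <- generate_cohort(cohort_spec(60, 120, seed = 11))
  grid <- build_benchmark_grid(base, sizes = c(20, 40, 60),
                               probabilities = c(1e-3, 1e-2), seed = 1)
  expect_length(grid, 6L)
  for (ds in grid) {
    prov <- attr(ds, "provenance")
    expect_identical(ncol(ds$corrupted), as.integer(prov$size))
    n <- length(ds$corrupted)
    ci <- qbinom(c(0.001, 0.999), n, prov$probability)
    expect_gte(sum(ds$mask), ci[1])
    expect_lte(sum(ds$mask), ci[2])
  }
  one <- build_benchmark_grid(base, sizes = 30, probabilities = 1e-2)
  expect_length(one, 1L)
  expect_error(build_benchmark_grid(base, sizes = 100,
                                    probabilities = 1e-3), "requests")
})

test_that("small-dataset subsampling keeps the anchors and sample counts", {
  m <- rand_counts(30, 119, seed = 12)
  keep <- colnames(m)[1:6]
  sizes <- c(110, 90, 60, 30, 20, 10)
  out <- subsample_small_datasets(m, keep, sizes, replicates = 10, seed = 2)
  expect_length(out, 60L)
  for (ds in out) {
    expect_true(all(keep %in% colnames(ds)))
    expect_false(anyDuplicated(colnames(ds)) > 0)
    expect_identical(ncol(ds), as.integer(attr(ds, "provenance")$size))
  }
  same <- subsample_small_datasets(m, keep, 6, replicates = 3, seed = 3)
  for (ds in same) expect_identical(sort(colnames(ds)), sort(keep))
  expect_error(subsample_small_datasets(m, keep, 5), ">=")
})
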