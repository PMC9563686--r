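# a linearly separable diagnostics fixture: AGE iff cooksD > 5
separable_fixture <- function(n = 200, seed = 1) {
  set.seed(seed)
  lab <- rep(c("NGE", "AGE"), each = n / 2)
  df <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    sample_id = "s1",
    typeerror = rnorm(n),
    dfbetas = abs(rnorm(n)),
    hat = runif(n, 0.05, 0.5),
    cooksD = ifelse(lab == "AGE", runif(n, 6, 30), runif(n, 0, 4)),
    stringsAsFactors = FALSE)
  class(df) <- c("diagnostics_table", "data.frame")
  list(diag = df, labels = factor(lab, levels = c("NGE", "AGE")))
}

test_that("CART separates a separable fixture with a single cooksD split", {
  fx <- separable_fixture()
  tr <- train_decision_tree(fx$diag, fx$labels, min_leaf = 5)
  pred <- predict_intervals(tr$intervals, fx$diag)
  expect_identical(pred, as.character(fx$labels))   # training accuracy 1

  # single split on cooksD between 4 and 6
  splits <- unlist(lapply(tr$intervals$rules, function(r)
    vapply(r$conditions, function(cond) cond$feature, "")))
  expect_true(all(splits == "cooksD"))
  thr <- tr$intervals$rules[[1]]$conditions[[1]]$threshold
  expect_gt(thr, 4); expect_lt(thr, 6)
  expect_length(tr$intervals$rules, 2L)   # depth-1 tree -> 2 rules
})

test_that("single-class labels raise the documented error", {
  fx <- separable_fixture()
  all_nge <- factor(rep("NGE", nrow(fx$diag)), levels = c("NGE", "AGE"))
  expect_error(train_decision_tree(fx$diag, all_nge),
               "injection probability")
})

test_that("interval extraction is faithful to the tree on random feature vectors", {
  inj <- tiny_labeled(seed = 31, n_samples = 25, n_genes = 150, p = 8e-3)
  f <- preprocess_counts(inj$corrupted,
                         estimate_size_factors(inj$corrupted))
  cfg <- vae_config(latent_dim = 5, hidden_sizes = c(32, 16, 12, 8),
                    epochs = 40, seed = 1)
  model <- train_vae(build_vae(cfg, nrow(inj$corrupted)), f, cfg)
  sp <- score_pair(inj$corrupted, reconstruct_counts(model, f))
  dg <- regression_diagnostics(sp)
  tr <- train_decision_tree(dg, mask_to_labels(dg, inj$mask))

  # at tau = 0.5 the rules reproduce the tree's majority predictions,
  # point for point on the training set
  df_train <- agescan:::clamp_features(as.data.frame(dg))
  tree_pred <- as.character(predict(tr$tree, df_train, type = "class"))
  expect_identical(predict_intervals(tr$intervals, df_train,
                                     relax_tau = 0.5), tree_pred)

  # ... and on 1e5 random feature vectors spanning the thresholds
  set.seed(99)
  rnd <- data.frame(typeerror = runif(1e5, -20, 20),
                    dfbetas = runif(1e5, 0, 10),
                    hat = runif(1e5, 0, 1),
                    cooksD = runif(1e5, 0, 50))
  expect_identical(predict_intervals(tr$intervals, rnd, relax_tau = 0.5),
                   as.character(predict(tr$tree, rnd, type = "class")))
  # the default decision is at least as strict as the majority vote
  strict <- predict_intervals(tr$intervals, rnd)
  expect_true(all(!(strict == "AGE" &
                    predict_intervals(tr$intervals, rnd,
                                      relax_tau = 0.5) == "NGE")))

  # every point matches exactly one rule
  match_count <- Reduce(`+`, lapply(tr$intervals$rules, function(r)
    as.integer(agescan:::rule_matches(r, rnd))))
  expect_true(all(match_count == 1L))
})

test_that("intervals survive a JSON round-trip with identical predictions", {
  fx <- separable_fixture(seed = 2)
  tr <- train_decision_tree(fx$diag, fx$labels, min_leaf = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_intervals(tr$intervals, path)
  back <- read_intervals(path)
  set.seed(5)
  rnd <- data.frame(typeerror = rnorm(500), dfbetas = abs(rnorm(500)),
                    hat = runif(500), cooksD = runif(500, 0, 40))
  expect_identical(predict_intervals(back, rnd),
                   predict_intervals(tr$intervals, rnd))
})

test_that("classification reports per-sample counts, errors on missing features, handles typical points", {
  fx <- separable_fixture(seed = 3)
  tr <- train_decision_tree(fx$diag, fx$labels, min_leaf = 5)
  cls <- classify_observations(fx$diag, tr$intervals)
  expect_identical(cls$label, as.character(fx$labels))
  expect_s3_class(attr(cls, "per_sample_age"), "table")

  # a perfectly typical point (all-zero diagnostics) is NGE
  typical <- data.frame(gene_id = "g", sample_id = "s", typeerror = 0,
                        dfbetas = 0, hat = 0, cooksD = 0)
  expect_identical(predict_intervals(tr$intervals, typical), "NGE")

  broken <- fx$diag; broken$cooksD <- NULL
  expect_error(classify_observations(broken, tr$intervals), "cooksD")
})

test_that("relaxed purity threshold can only widen the AGE set", {
  inj <- tiny_labeled(seed = 41, n_samples = 25, n_genes = 120, p = 8e-3)
  f <- preprocess_counts(inj$corrupted,
                         estimate_size_factors(inj$corrupted))
  cfg <- vae_config(latent_dim = 5, hidden_sizes = c(32, 16, 12, 8),
                    epochs = 30, seed = 1)
  model <- train_vae(build_vae(cfg, nrow(inj$corrupted)), f, cfg)
  sp <- score_pair(inj$corrupted, reconstruct_counts(model, f))
  dg <- regression_diagnostics(sp)
  tr <- train_decision_tree(dg, mask_to_labels(dg, inj$mask))
  strict <- classify_observations(dg, tr$intervals)
  relaxed <- classify_observations(dg, tr$intervals, relax_tau = 0.2)
  expect_true(all(which(strict$label == "AGE") %in%
                  which(relaxed$label == "AGE")))
})

test_that("when every AGE leaf requires large cooksD, boosting cooksD never flips AGE to NGE", {
  fx <- separable_fixture(seed = 7)
  tr <- train_decision_tree(fx$diag, fx$labels, min_leaf = 5)
  age_conds <- unlist(lapply(Filter(function(r) r$label == "AGE",
                                    tr$intervals$rules),
                             function(r) sapply(r$conditions, function(cond)
                               paste(cond$feature, cond$op))))
  expect_true(all(age_conds == "cooksD >="))   # precondition of the property

  thrs <- unlist(lapply(tr$intervals$rules, function(r)
    vapply(r$conditions, function(cond) cond$threshold, 0)))
  big <- max(abs(thrs)) + 1
  set.seed(6)
  base <- data.frame(typeerror = rnorm(500), dfbetas = abs(rnorm(500)),
                     hat = runif(500), cooksD = runif(500, 0, 30))
  p1 <- predict_intervals(tr$intervals, base)
  boosted <- base; boosted$cooksD <- boosted$cooksD + 10 * big
  p2 <- predict_intervals(tr$intervals, boosted)
  expect_false(any(p1 == "AGE" & p2 == "NGE"))
})

test_that("shipped default intervals load, partition the feature space, and honor their purity threshold", {
  iv <- default_intervals()
  expect_s3_class(iv, "age_intervals")
  expect_gt(length(iv$rules), 1L)
  for (r in iv$rules)
    expect_identical(r$label,
                     if (r$purity_age >= iv$decision_tau) "AGE" else "NGE")
  set.seed(8)
  rnd <- data.frame(typeerror = runif(2e4, -30, 30),
                    dfbetas = runif(2e4, 0, 20),
                    hat = runif(2e4, 0, 1), cooksD = runif(2e4, 0, 100))
  matches <- Reduce(`+`, lapply(iv$rules, function(r)
    as.integer(agescan:::rule_matches(r, rnd))))
  expect_true(all(matches == 1L))
  expect_true(any(predict_intervals(iv, rnd) == "AGE"))
})
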