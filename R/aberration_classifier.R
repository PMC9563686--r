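DIAG_FEATURES <- c("typeerror", "dfbetas", "hat", "cooksD")

#' Attach ground-truth labels to a diagnostics table
#'
#' @param diag A `diagnostics_table`.
#' @param mask Logical genes x samples injection mask (TRUE = aberrant).
#' @return Factor of levels `c("NGE", "AGE")` aligned to `diag`'s rows.
#' @export
mask_to_labels <- function(diag, mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  idx <- cbind(match(diag$gene_id, rownames(mask)),
               match(diag$sample_id, colnames(mask)))
  if (anyNA(idx))
    stop("diagnostics rows not covered by the mask's gene/sample universe")
  factor(ifelse(mask[idx], "AGE", "NGE"), levels = c("NGE", "AGE"))
}

# rpart chokes on the infinite-influence sentinels; clamp symmetrically in
# training and rule application so thresholds stay comparable
clamp_features <- function(df, bound = 1e10) {
  for (f in intersect(DIAG_FEATURES, names(df))) {
    v <- df[[f]]
    v[is.nan(v)] <- 0
    df[[f]] <- pmin(pmax(v, -bound), bound)
  }
  df
}

#' Train the CART aberration classifier
#'
#' Fits a CART decision tree (Gini impurity) on the four regression
#' diagnostics of a labeled semi-synthetic dataset and extracts its
#' root-to-leaf paths as interval rules. Because injected aberrations are
#' extremely rare, observations are weighted so both classes carry equal
#' total weight ("balanced"); without this the tree collapses to all-NGE.
#'
#' @param diag A `diagnostics_table`.
#' @param labels Factor/character of `"AGE"`/`"NGE"` per row (see
#'   [mask_to_labels()]), or a logical genes x samples mask.
#' @param max_depth Maximum tree depth (default 6).
#' @param min_leaf Minimum observations per leaf (default 20).
#' @param class_weight `"balanced"` (default) or `"none"`.
#' @param cp Complexity parameter passed to rpart (default 1e-4; growth is
#'   bounded by depth and leaf size instead).
#' @param decision_tau Rebalanced-purity threshold above which a leaf is
#'   labeled AGE (default 0.9). Because classes are weighted to equal mass,
#'   a leaf's rebalanced purity p corresponds to a p/(1-p)-fold enrichment
#'   of aberrations over their prevalence; the default therefore calls a
#'   region aberrant only when injections are about 9-fold enriched there.
#'   `decision_tau = 0.5` is the tree's plain majority vote, which in this
#'   extremely imbalanced setting flags any region merely at prevalence
#'   odds and floods the output with calls.
#' @param seed Integer seed (CART is deterministic; kept for the manifest).
#' @return List of class `age_tree` with the fitted `rpart` object, the
#'   extracted `intervals` ([extract_intervals()]) and training metadata.
#' @export
train_decision_tree <- function(diag, labels, max_depth = 6L, min_leaf = 20L,
                                class_weight = c("balanced", "none"),
                                cp = 1e-4, decision_tau = 0.9, seed = 1L) {
  class_weight <- match.arg(class_weight)
  if (is.logical(labels) && is.matrix(labels))
    labels <- mask_to_labels(diag, labels)
  labels <- factor(as.character(labels), levels = c("NGE", "AGE"))
  if (anyNA(labels)) stop("labels must be 'AGE' or 'NGE'")
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class; the semi-synthetic ",
         "dataset has no injected aberrations - raise the injection ",
         "probability")
  df <- clamp_features(as.data.frame(diag)[DIAG_FEATURES])
  df$label <- labels
  tab <- table(labels)
  w <- if (class_weight == "balanced")
         as.numeric(length(labels) / (2 * tab[as.character(labels)]))
       else rep(1, length(labels))
  set.seed(seed)
  tree <- rpart::rpart(label ~ typeerror + dfbetas + hat + cooksD,
                       data = df, weights = w, method = "class",
                       parms = list(split = "gini"),
                       control = rpart::rpart.control(
                         maxdepth = max_depth, minbucket = min_leaf,
                         minsplit = 2L * min_leaf, cp = cp, xval = 0L,
                         maxcompete = 0L, maxsurrogate = 0L,
                         usesurrogate = 0L))
  intervals <- extract_intervals(tree, decision_tau = decision_tau,
    meta = list(seed = seed, max_depth = max_depth, min_leaf = min_leaf,
                class_weight = class_weight, cp = cp,
                decision_tau = decision_tau,
                n_train = length(labels), n_age = unname(tab["AGE"])))
  structure(list(tree = tree, intervals = intervals,
                 class_balance = as.list(tab)),
            class = "age_tree")
}

#' Extract interval rules from a fitted CART tree
#'
#' Enumerates every root-to-leaf path of the tree as a conjunction of
#' threshold conditions over the diagnostic features. The rules are
#' exhaustive and mutually exclusive: every feature vector matches exactly
#' one rule. Each rule carries its AGE purity (class-rebalanced leaf
#' probability) and a label set by `decision_tau`; applying `relax_tau =
#' 0.5` downstream reproduces the tree's own majority predictions exactly.
#'
#' @param tree An `rpart` classification tree over the diagnostic features
#'   (or an `age_tree`).
#' @param decision_tau Purity threshold used for the stored labels
#'   (default 0.9; see [train_decision_tree()]).
#' @param meta Optional training metadata stored alongside the rules.
#' @return An object of class `age_intervals`: list of rules, each with
#'   `conditions` (feature, op in `<` / `>=`, threshold), `label`,
#'   `purity_age` and `n`.
#' @export
extract_intervals <- function(tree, decision_tau = 0.9, meta = list()) {
  if (inherits(tree, "age_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "rpart"))
  frame <- tree$frame
  ylev <- attr(tree, "ylevels")
  nodes <- as.integer(rownames(frame))
  agecol <- which(ylev == "AGE")
  # yval2 columns for a 2-class tree: yval, n per class, prob per class, nodewt
  probs <- frame$yval2[, 1L + length(ylev) + seq_along(ylev), drop = FALSE]

  splits <- tree$splits
  # with maxcompete = maxsurrogate = 0 there is exactly one splits row per
  # internal node, in frame order
  internal <- which(frame$var != "<leaf>")
  split_row <- integer(nrow(frame))
  split_row[internal] <- seq_along(internal)

  rules <- list()
  walk <- function(node_id, conds) {
    i <- match(node_id, nodes)
    if (frame$var[i] == "<leaf>") {
      p_age <- if (length(agecol)) unname(probs[i, agecol]) else 0
      rules[[length(rules) + 1L]] <<- list(
        conditions = conds,
        label = if (p_age >= decision_tau) "AGE" else "NGE",
        purity_age = p_age,
        n = frame$n[i])
      return(invisible(NULL))
    }
    sp <- splits[split_row[i], , drop = TRUE]
    feat <- as.character(frame$var[i])
    thr <- unname(sp["index"])
    if (sp["ncat"] < 0) {        # left child: feature < threshold
      left <- list(feature = feat, op = "<", threshold = thr)
      right <- list(feature = feat, op = ">=", threshold = thr)
    } else {                     # left child: feature >= threshold
      left <- list(feature = feat, op = ">=", threshold = thr)
      right <- list(feature = feat, op = "<", threshold = thr)
    }
    walk(node_id * 2L, c(conds, list(left)))
    walk(node_id * 2L + 1L, c(conds, list(right)))
  }
  walk(1L, list())
  structure(list(rules = rules, features = DIAG_FEATURES,
                 decision_tau = decision_tau, meta = meta),
            class = "age_intervals")
}

rule_matches <- function(rule, df) {
  ok <- rep(TRUE, nrow(df))
  for (cond in rule$conditions) {
    v <- df[[cond$feature]]
    ok <- ok & if (cond$op == "<") v < cond$threshold else v >= cond$threshold
  }
  ok
}

#' Classify observations with extracted interval rules
#'
#' Each (gene, sample) row of the diagnostics table is labeled by the single
#' rule its features satisfy. With `relax_tau`, a leaf is labeled AGE
#' whenever its training AGE purity reaches `relax_tau` instead of the
#' stored decision threshold — lowering it recovers borderline aberrations
#' at the cost of more calls (`relax_tau = 0.5` is the tree's plain
#' majority vote).
#'
#' @param diag A `diagnostics_table` (or data.frame with the four features).
#' @param intervals An `age_intervals` object.
#' @param relax_tau Optional AGE-purity threshold in (0, 1]; `NULL`
#'   (default) uses the labels stored at training time.
#' @return Data.frame (gene_id, sample_id, label) with a `per_sample_age`
#'   attribute counting AGE calls per sample.
#' @export
classify_observations <- function(diag, intervals, relax_tau = NULL) {
  stopifnot(inherits(intervals, "age_intervals"))
  missing <- setdiff(intervals$features, names(diag))
  if (length(missing))
    stop("diagnostics table lacks feature(s): ",
         paste(missing, collapse = ", "))
  df <- clamp_features(as.data.frame(diag))
  lab <- rep(NA_character_, nrow(df))
  for (rule in intervals$rules) {
    hit <- rule_matches(rule, df) & is.na(lab)
    lab[hit] <- if (!is.null(relax_tau)) {
      if (rule$purity_age >= relax_tau) "AGE" else "NGE"
    } else rule$label
  }
  if (anyNA(lab)) stop("interval rules failed to cover every observation")
  out <- data.frame(gene_id = df$gene_id, sample_id = df$sample_id,
                    label = lab, stringsAsFactors = FALSE)
  attr(out, "per_sample_age") <-
    table(factor(out$sample_id[out$label == "AGE"],
                 levels = unique(df$sample_id)))
  out
}

#' Predict labels for raw feature vectors
#'
#' Rule-based prediction on a plain data.frame holding the four diagnostic
#' features; used to verify that the extracted intervals reproduce the
#' tree's own predictions.
#'
#' @param intervals An `age_intervals`.
#' @param features Data.frame with columns typeerror, dfbetas, hat, cooksD.
#' @param relax_tau Optional purity threshold, as in
#'   [classify_observations()].
#' @return Character vector of `"AGE"`/`"NGE"`.
#' @export
predict_intervals <- function(intervals, features, relax_tau = NULL) {
  df <- clamp_features(features)
  lab <- rep(NA_character_, nrow(df))
  for (rule in intervals$rules) {
    hit <- rule_matches(rule, df) & is.na(lab)
    lab[hit] <- if (!is.null(relax_tau)) {
      if (rule$purity_age >= relax_tau) "AGE" else "NGE"
    } else rule$label
  }
  if (anyNA(lab)) stop("interval rules failed to cover every observation")
  lab
}

#' Serialize / restore interval rules as JSON
#'
#' @param intervals An `age_intervals`.
#' @param path Output file.
#' @return `write_intervals` returns `path` invisibly; `read_intervals`
#'   the restored `age_intervals`.
#' @export
write_intervals <- function(intervals, path) {
  stopifnot(inherits(intervals, "age_intervals"))
  jsonlite::write_json(unclass(intervals), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("intervals file does not exist: ", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$rules <- lapply(x$rules, function(r) {
    r$conditions <- lapply(r$conditions, function(cond) {
      cond$threshold <- as.numeric(cond$threshold)
      cond
    })
    r$purity_age <- as.numeric(r$purity_age)
    r
  })
  x$features <- as.character(unlist(x$features))
  x$decision_tau <- as.numeric(x$decision_tau %||% 0.9)
  structure(x, class = "age_intervals")
}

#' Default interval rules shipped with the package
#'
#' Rules trained on a packaged synthetic semi-synthetic cohort (a stand-in
#' labeled as such; see the file `synthetic_default_intervals.json` under
#' `extdata`). They allow the unsupervised phase to run without re-running
#' supervised training, at the cost of being calibrated on simulated rather
#' than real data.
#'
#' @return An `age_intervals` object.
#' @export
default_intervals <- function() {
  path <- system.file("extdata", "synthetic_default_intervals.json",
                      package = "agescan", mustWork = TRUE)
  read_intervals(path)
}

#' @export
print.age_intervals <- function(x, ...) {
  cat("Aberration interval rules (", length(x$rules), " leaves)\n", sep = "")
  for (r in x$rules) {
    conds <- if (length(r$conditions))
      paste(vapply(r$conditions, function(cond)
        paste(cond$feature, cond$op, signif(cond$threshold, 4)), ""),
        collapse = " & ")
    else "(root)"
    cat(sprintf("  %-4s p(AGE)=%.3f n=%-6d %s\n", r$label, r$purity_age,
                r$n, conds))
  }
  invisible(x)
}
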