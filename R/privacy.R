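#' Single membership-inference attack
#'
#' Labels the rows of the two logit sets by membership (training vs
#' held-out), balances the class sizes by subsampling the larger set,
#' splits the merged data into a stratified 80/20 attack train/evaluation
#' split, fits a 50-tree random-forest classifier, and reports the attack
#' AUROC on the evaluation split together with the impurity-based feature
#' importances (normalized to sum to 1). An attack AUROC near 0.5 means
#' the model's outputs do not betray membership.
#'
#' @param train_logits,heldout_logits Numeric matrices with the same number
#'   of columns (model output logits or probabilities; both are accepted —
#'   the attack is representation-agnostic).
#' @param n_trees Number of trees (default 50).
#' @param split Fraction of the merged data used to train the attacker
#'   (default 0.8).
#' @param seed Integer seed controlling the subsampling, the split, and the
#'   forest.
#' @return List with `auroc`, `importances`, `n_per_class`, `seed`.
#' @export
mia_single <- function(train_logits, heldout_logits, n_trees = 50,
                       split = 0.8, seed = NULL) {
  train_logits <- as.matrix(train_logits)
  heldout_logits <- as.matrix(heldout_logits)
  if (ncol(train_logits) != ncol(heldout_logits))
    stop_ecg("feature dimensions differ: %d vs %d", ncol(train_logits),
             ncol(heldout_logits))
  if (nrow(train_logits) < 10 || nrow(heldout_logits) < 10)
    stop_ecg("each logit set needs at least 10 rows")
  with_seed(seed, {
    m <- min(nrow(train_logits), nrow(heldout_logits))
    if (nrow(train_logits) > m)
      train_logits <- train_logits[sample.int(nrow(train_logits), m), , drop = FALSE]
    if (nrow(heldout_logits) > m)
      heldout_logits <- heldout_logits[sample.int(nrow(heldout_logits), m), , drop = FALSE]
    X <- rbind(train_logits, heldout_logits)
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    y <- factor(rep(c("member", "nonmember"), each = m))
    tr_idx <- c(sample.int(m, round(split * m)),
                m + sample.int(m, round(split * m)))
    rf <- randomForest::randomForest(x = X[tr_idx, , drop = FALSE],
                                     y = y[tr_idx], ntree = n_trees)
    prob <- predict(rf, X[-tr_idx, , drop = FALSE], type = "prob")[, "member"]
    att_auc <- auroc(as.integer(y[-tr_idx] == "member"), prob)
    imp <- randomForest::importance(rf)[, 1]
    imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
    list(auroc = att_auc, importances = imp, n_per_class = m, seed = seed)
  })
}

#' Repeated membership-inference attack with predefined seeds
#'
#' Runs [mia_single()] once per seed, then reports the mean attack AUROC
#' with an empirical 95 percent interval over the repeats and the
#' elementwise average of the per-repeat feature importances.
#'
#' @inheritParams mia_single
#' @param seeds Integer vector of predefined seeds (default `0:9`,
#'   ten repeats).
#' @return An object of class `attack_report`.
#' @export
mia_repeated <- function(train_logits, heldout_logits, seeds = 0:9,
                         n_trees = 50, split = 0.8) {
  if (length(seeds) < 2) stop_ecg("need at least two seeds")
  runs <- lapply(seeds, function(s)
    mia_single(train_logits, heldout_logits, n_trees, split, seed = s))
  aucs <- vapply(runs, `[[`, numeric(1), "auroc")
  imps <- do.call(rbind, lapply(runs, `[[`, "importances"))
  ci <- quantile(aucs, c(0.025, 0.975), names = FALSE)
  structure(list(per_repeat_auroc = aucs, mean_auroc = mean(aucs),
                 ci_low = ci[1], ci_high = ci[2],
                 feature_importances = colMeans(imps),
                 split_fraction = split, n_trees = n_trees,
                 seeds = seeds),
            class = "attack_report")
}

#' @export
print.attack_report <- function(x, ...) {
  cat(sprintf("<attack_report> mean attack AUROC %.3f (95%% CI %.3f-%.3f over %d seeded repeats)\n",
              x$mean_auroc, x$ci_low, x$ci_high, length(x$seeds)))
  cat(sprintf("  top feature: %s (importance %.3f)\n",
              names(which.max(x$feature_importances)) %||%
                which.max(x$feature_importances),
              max(x$feature_importances)))
  invisible(x)
}

#' t-SNE train/held-out separation diagnostic
#'
#' Samples up to `sample_per_set` rows from each logit set, embeds the
#' combined sample in two dimensions with t-SNE (perplexity 30 by default),
#' and scores how separated the two memberships are in the embedding with
#' the mean silhouette width of the membership tags. The silhouette score
#' is a diagnostic added by this toolkit (not a standard re-identification
#' quantity): near 0 means the clouds overlap, values toward 1 mean the
#' sets occupy distinct regions and are thus more re-identifiable. For
#' tractability the silhouette is computed on a seeded subsample of at most
#' `silhouette_max` embedded points (its O(n^2) distance matrix is the
#' constraint); coordinates are returned for all embedded points.
#'
#' @inheritParams mia_single
#' @param sample_per_set Rows sampled from each set (default 10000; sets
#'   smaller than this are used whole, and that is recorded in the output).
#' @param perplexity t-SNE perplexity (default 30); must be smaller than
#'   the sample size.
#' @param seed Integer seed.
#' @param silhouette_max Cap on points used for the silhouette score
#'   (default 2000).
#' @return List with `coords` (n x 2), `membership` (factor),
#'   `separation_score`, `n_used`, `subsampled`, `perplexity`, `seed`.
#' @export
tsne_separation <- function(train_logits, heldout_logits,
                            sample_per_set = 10000, perplexity = 30,
                            seed = NULL, silhouette_max = 2000) {
  train_logits <- as.matrix(train_logits)
  heldout_logits <- as.matrix(heldout_logits)
  if (ncol(train_logits) != ncol(heldout_logits))
    stop_ecg("feature dimensions differ")
  with_seed(seed, {
    take <- function(x) {
      if (nrow(x) > sample_per_set)
        x[sample.int(nrow(x), sample_per_set), , drop = FALSE] else x
    }
    a <- take(train_logits); b <- take(heldout_logits)
    n_used <- c(train = nrow(a), heldout = nrow(b))
    X <- rbind(a, b)
    if (perplexity >= nrow(X))
      stop_ecg("perplexity (%g) must be smaller than the sample size (%d)",
               perplexity, nrow(X))
    if (3 * perplexity > nrow(X) - 1)
      stop_ecg("sample too small for perplexity %g (need > %d points)",
               perplexity, 3 * perplexity + 1)
    emb <- Rtsne::Rtsne(X, dims = 2, perplexity = perplexity,
                        check_duplicates = FALSE, pca = TRUE,
                        verbose = FALSE)$Y
    membership <- factor(rep(c("train", "heldout"), times = n_used))
    idx <- if (nrow(emb) > silhouette_max)
      sort(sample.int(nrow(emb), silhouette_max)) else seq_len(nrow(emb))
    sil <- cluster::silhouette(as.integer(membership[idx]),
                               stats::dist(emb[idx, , drop = FALSE]))
    list(coords = emb, membership = membership,
         separation_score = mean(sil[, "sil_width"]),
         n_used = n_used,
         subsampled = any(n_used < c(nrow(train_logits), nrow(heldout_logits))),
         perplexity = perplexity, seed = seed)
  })
}
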