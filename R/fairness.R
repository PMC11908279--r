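#' Assign ages to the audit's three age groups
#'
#' Groups are under 55, 55-75, and over 75. The band edges are read
#' inclusively for the middle group: ages of exactly 55 or 75 fall in
#' `55_75`.
#'
#' @param age Numeric vector of ages in years (must be non-negative).
#' @return Factor with levels `under_55`, `55_75`, `over_75`.
#' @export
assign_age_group <- function(age) {
  if (anyNA(age) || any(age < 0)) stop_ecg("ages must be non-negative")
  out <- ifelse(age < 55, "under_55", ifelse(age <= 75, "55_75", "over_75"))
  factor(out, levels = c("under_55", "55_75", "over_75"))
}

grouping_vector <- function(predset, grouping) {
  if (grouping == "sex") {
    if (is.null(predset$sex)) stop_ecg("prediction set carries no sex field")
    factor(predset$sex)
  } else {
    if (is.null(predset$age)) stop_ecg("prediction set carries no age field")
    assign_age_group(predset$age)
  }
}

# Per-record pooled cell counts at frozen thresholds: tp/pos/fp/neg summed
# over labels, the building blocks of micro-averaged group rates.
cell_counts <- function(predset, thresholds) {
  preds <- apply_thresholds(predset, thresholds)
  ok <- !is.na(thresholds)
  y <- predset$labels[, ok, drop = FALSE]
  p <- preds[, ok, drop = FALSE]
  cbind(tp = rowSums(y == 1 & p == 1), pos = rowSums(y == 1),
        fp = rowSums(y == 0 & p == 1), neg = rowSums(y == 0))
}

#' Micro-averaged TPR/FPR per demographic group
#'
#' Within each group, all (record, label) cells are pooled before computing
#' the rates (micro-averaging): `TPR = sum TP / sum positives`,
#' `FPR = sum FP / sum negatives`, at the supplied frozen thresholds.
#' Empty groups are dropped with a warning.
#'
#' @param predset A [prediction_set()] with the relevant demographic field.
#' @param thresholds Per-label thresholds (see [select_thresholds()]).
#' @param grouping `"sex"` or `"age"` (three bins via [assign_age_group()]).
#' @return Data frame with columns `group`, `n`, `tpr`, `fpr`.
#' @export
group_rates <- function(predset, thresholds, grouping = c("sex", "age")) {
  grouping <- match.arg(grouping)
  g <- grouping_vector(predset, grouping)
  counts <- cell_counts(predset, thresholds)
  agg <- rowsum(counts, g)
  n_per <- as.vector(table(g)[rownames(agg)])
  empty <- n_per == 0
  if (any(empty)) {
    warning(sprintf("empty group(s) excluded: %s",
                    paste(rownames(agg)[empty], collapse = ", ")),
            call. = FALSE)
    agg <- agg[!empty, , drop = FALSE]; n_per <- n_per[!empty]
  }
  data.frame(group = rownames(agg), n = n_per,
             tpr = ifelse(agg[, "pos"] > 0, agg[, "tp"] / agg[, "pos"], NA),
             fpr = ifelse(agg[, "neg"] > 0, agg[, "fp"] / agg[, "neg"], NA),
             row.names = NULL)
}

mean_abs_pairwise <- function(x) {
  if (length(x) < 2) return(NA_real_)
  pairs <- utils::combn(x, 2)
  mean(abs(pairs[1, ] - pairs[2, ]))
}

#' Equalized-odds disparity bootstrap
#'
#' The audit protocol for equalized odds: in each of `iterations`
#' iterations, 70 percent of the records are sampled (without replacement),
#' micro-averaged TPR and FPR are computed for each group at the frozen
#' thresholds, and the disparity is the mean absolute difference over all
#' unordered group pairs (with two groups this is simply
#' `|rate_A - rate_B|`). The report carries the mean disparity and the
#' empirical 95 percent interval over iterations, separately for TPR and
#' FPR. Iterations in which a group vanishes or a rate is undefined are
#' redrawn (logged), never propagated as NaN.
#'
#' @inheritParams group_rates
#' @param fraction Subsample fraction (default 0.7).
#' @param iterations Resampling iterations (default 1000).
#' @param seed Integer seed.
#' @return An object of class `fairness_report`.
#' @export
disparity_bootstrap <- function(predset, thresholds,
                                grouping = c("sex", "age"), fraction = 0.7,
                                iterations = 1000, seed = NULL) {
  grouping <- match.arg(grouping)
  g <- grouping_vector(predset, grouping)
  g <- droplevels(g)
  if (nlevels(g) < 2) stop_ecg("need at least two non-empty groups")
  counts <- cell_counts(predset, thresholds)
  n <- nrow(counts)
  m <- max(1L, floor(fraction * n))
  redraws <- 0L
  one_iter <- function() {
    for (try in 1:10) {
      idx <- sample.int(n, m)
      gi <- g[idx]
      if (nlevels(droplevels(gi)) < nlevels(g)) { redraws <<- redraws + 1L; next }
      agg <- rowsum(counts[idx, , drop = FALSE], gi)
      if (any(agg[, "pos"] == 0) || any(agg[, "neg"] == 0)) {
        redraws <<- redraws + 1L; next
      }
      return(c(tpr = mean_abs_pairwise(agg[, "tp"] / agg[, "pos"]),
               fpr = mean_abs_pairwise(agg[, "fp"] / agg[, "neg"])))
    }
    stop_ecg("a resampling iteration kept losing a group after 10 redraws")
  }
  disp <- with_seed(seed,
                    vapply(seq_len(iterations), function(i) one_iter(),
                           numeric(2)))
  tpr_ci <- quantile(disp["tpr", ], c(0.025, 0.975), names = FALSE)
  fpr_ci <- quantile(disp["fpr", ], c(0.025, 0.975), names = FALSE)
  structure(list(grouping = grouping, groups = levels(g),
                 mean_abs_tpr_disparity = mean(disp["tpr", ]),
                 tpr_ci_low = tpr_ci[1], tpr_ci_high = tpr_ci[2],
                 mean_abs_fpr_disparity = mean(disp["fpr", ]),
                 fpr_ci_low = fpr_ci[1], fpr_ci_high = fpr_ci[2],
                 max_abs_tpr_disparity = max(disp["tpr", ]),
                 max_abs_fpr_disparity = max(disp["fpr", ]),
                 iterations = iterations, fraction = fraction, seed = seed,
                 n_redraws = redraws,
                 group_rates = group_rates(predset, thresholds, grouping)),
            class = "fairness_report")
}

#' @export
print.fairness_report <- function(x, ...) {
  cat(sprintf("<fairness_report> by %s (%s)\n", x$grouping,
              paste(x$groups, collapse = ", ")))
  cat(sprintf("  mean |TPR disparity| %.4f (95%% CI %.4f-%.4f)\n",
              x$mean_abs_tpr_disparity, x$tpr_ci_low, x$tpr_ci_high))
  cat(sprintf("  mean |FPR disparity| %.4f (95%% CI %.4f-%.4f)\n",
              x$mean_abs_fpr_disparity, x$fpr_ci_low, x$fpr_ci_high))
  invisible(x)
}
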