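check_binary_both <- function(labels, what = "label") {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop_ecg("%s vector must be binary 0/1", what)
  if (all(labels == 1) || all(labels == 0))
    stop_ecg("degenerate %s vector: all values are %d", what, labels[1])
  labels
}

#' Rank-based AUROC
#'
#' Midrank (Mann-Whitney) estimator: ties between a positive and a negative
#' score receive half credit, so the value equals the exhaustive
#' pair-counting probability `P(score+ > score-) + 0.5 P(score+ = score-)`
#' exactly.
#'
#' @param labels Binary vector with both classes present.
#' @param scores Numeric score vector of equal length.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- check_binary_both(labels)
  stopifnot(length(labels) == length(scores))
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration over the unique score thresholds (descending): at each
#' threshold the precision is weighted by the recall increment, which is
#' tie-safe and equals the standard average-precision estimator.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(labels, scores) {
  labels <- check_binary_both(labels)
  stopifnot(length(labels) == length(scores))
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)  # threshold boundaries
  tp <- tp[last_of_block]; fp <- fp[last_of_block]
  P <- sum(labels)
  prec <- tp / (tp + fp); rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Overall (concatenated) AUROC of a multilabel prediction set
#'
#' Flattens all (record, label) cells of the score and label matrices into
#' single vectors and computes one micro AUROC over them, giving a global
#' performance number across all labels at once.
#'
#' @param predset A [prediction_set()].
#' @return AUROC in `[0, 1]`.
#' @export
overall_auroc <- function(predset) {
  stopifnot(inherits(predset, "prediction_set"))
  y <- as.vector(predset$labels); s <- as.vector(predset$scores)
  if (all(y == 1) || all(y == 0))
    stop_ecg("all labels are degenerate (flattened label vector is single-class)")
  auroc(y, s)
}

#' Subsample confidence interval for any prediction-set metric
#'
#' Each of `iterations` iterations draws `floor(fraction * n)` records —
#' without replacement by default (70 percent subsampling), with
#' replacement if `replace = TRUE` — and recomputes `metric` on the
#' subsample. The 95 percent interval is the empirical 2.5/97.5 percentile
#' of the iteration values; the point estimate is the metric on the full
#' set. Iterations on which the metric errors (e.g. a degenerate label in
#' the subsample) are redrawn, at most 10 times each, so the iteration
#' count stays exact.
#'
#' @param predset A [prediction_set()].
#' @param metric Function `prediction_set -> number`.
#' @param fraction Subsample fraction in (0, 1] (default 0.7).
#' @param iterations Number of resampling iterations (default 1000).
#' @param seed Integer seed for reproducibility.
#' @param replace Draw with replacement (default `FALSE`).
#' @return An object of class `metric_estimate` with fields `point`,
#'   `ci_low`, `ci_high`, `values`, `n_iterations`, `sample_fraction`,
#'   `seed`, `n_redraws`.
#' @export
bootstrap_metric <- function(predset, metric, fraction = 0.7,
                             iterations = 1000, seed = NULL,
                             replace = FALSE) {
  stopifnot(inherits(predset, "prediction_set"), is.function(metric))
  if (fraction <= 0 || fraction > 1) stop_ecg("`fraction` must lie in (0, 1]")
  n <- nrow(predset$scores)
  m <- max(1L, floor(fraction * n))
  point <- metric(predset)
  redraws <- 0L
  vals <- with_seed(seed, vapply(seq_len(iterations), function(i) {
    for (try in 1:10) {
      idx <- sample.int(n, m, replace = replace)
      v <- tryCatch(metric(subset_records(predset, idx)),
                    error = function(e) NA_real_)
      if (!is.na(v)) return(v)
      redraws <<- redraws + 1L
    }
    stop_ecg("iteration %d still degenerate after 10 redraws", i)
  }, numeric(1)))
  ci <- quantile(vals, c(0.025, 0.975), names = FALSE)
  structure(list(point = point, ci_low = ci[1], ci_high = ci[2],
                 values = vals, n_iterations = iterations,
                 sample_fraction = fraction, seed = seed,
                 n_redraws = redraws),
            class = "metric_estimate")
}

#' @export
print.metric_estimate <- function(x, ...) {
  cat(sprintf("%.4f (95%% CI %.4f-%.4f; %d x %g%% subsamples)\n",
              x$point, x$ci_low, x$ci_high, x$n_iterations,
              100 * x$sample_fraction))
  invisible(x)
}

# Structural components V10 (per positive) and V01 (per negative) of the
# Mann-Whitney statistic, computed by direct pair comparison. O(n1*n0);
# intended for the evaluation set sizes this toolkit targets.
delong_components <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), theta = mean(cmp))
}

#' DeLong test for two correlated AUROCs
#'
#' Compares the AUROCs of two score vectors evaluated on the same records
#' and labels, using the DeLong covariance estimate for paired
#' (correlated) Mann-Whitney statistics; returns a two-sided normal
#' p-value. When the two score vectors induce identical rankings the
#' variance of the difference is zero; that degenerate case returns
#' `p = 1` with `degenerate = TRUE` rather than a division by zero.
#'
#' @param labels Binary vector with both classes present.
#' @param scores_a,scores_b Paired score vectors on the same records.
#' @return List with `auroc_a`, `auroc_b`, `p_value`, `z`, `degenerate`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  labels <- check_binary_both(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  ca <- delong_components(labels, scores_a)
  cb <- delong_components(labels, scores_b)
  m <- sum(labels == 1); n <- sum(labels == 0)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (v <= .Machine$double.eps) {
    return(list(auroc_a = ca$theta, auroc_b = cb$theta, p_value = 1,
                z = 0, degenerate = TRUE))
  }
  z <- (ca$theta - cb$theta) / sqrt(v)
  list(auroc_a = ca$theta, auroc_b = cb$theta,
       p_value = 2 * pnorm(-abs(z)), z = z, degenerate = FALSE)
}

select_threshold_single <- function(labels, scores) {
  o <- order(scores)
  s <- scores[o]; y <- labels[o]
  u <- unique(s)
  P <- sum(y); N <- length(y) - P
  cpos <- cumsum(y); cneg <- cumsum(1 - y)
  first <- match(u, s)
  below_pos <- c(0, cpos[first[-1] - 1])   # positives strictly below u_k
  below_neg <- c(0, cneg[first[-1] - 1])
  sens <- (P - below_pos) / P              # preds: score >= u_k
  spec <- below_neg / N
  bal <- (sens + spec) / 2
  k <- which(bal == max(bal))[1L]          # lowest optimal candidate
  lo <- if (k == 1L) 0 else u[k - 1L]
  list(threshold = (lo + u[k]) / 2, balanced_accuracy = max(bal))
}

#' Select per-label thresholds maximizing balanced accuracy
#'
#' For every label, scans all unique scores as candidate thresholds
#' (predicted positive when `score >= t`) and keeps the one maximizing the
#' mean of sensitivity and specificity. When several thresholds tie, the
#' midpoint of the lowest optimal interval — between the optimal candidate
#' and the next score below it (0 when none) — is returned, which is
#' deterministic and symmetric. Thresholds are meant to be frozen on a
#' training set and applied unchanged to every other dataset.
#'
#' @param train_predset A [prediction_set()] used to fit thresholds.
#' @return Named numeric vector of thresholds, `NA` for degenerate labels
#'   (reported with a warning).
#' @export
select_thresholds <- function(train_predset) {
  stopifnot(inherits(train_predset, "prediction_set"))
  L <- ncol(train_predset$scores)
  th <- rep(NA_real_, L)
  names(th) <- train_predset$label_names
  for (j in seq_len(L)) {
    y <- train_predset$labels[, j]
    if (all(y == 1) || all(y == 0)) next
    th[j] <- select_threshold_single(y, train_predset$scores[, j])$threshold
  }
  if (anyNA(th))
    warning(sprintf("threshold undefined for degenerate label(s): %s",
                    paste(names(th)[is.na(th)], collapse = ", ")),
            call. = FALSE)
  th
}

#' Binarize a prediction set at frozen thresholds
#'
#' @param predset A [prediction_set()].
#' @param thresholds Per-label threshold vector (from
#'   [select_thresholds()]); predicted positive when `score >= t`.
#' @return Binary `n x L` matrix.
#' @export
apply_thresholds <- function(predset, thresholds) {
  stopifnot(inherits(predset, "prediction_set"),
            length(thresholds) == ncol(predset$scores))
  preds <- sweep(predset$scores, 2, thresholds, ">=") * 1L
  preds[, is.na(thresholds)] <- NA_integer_
  preds
}

#' Confusion rates of binary predictions
#'
#' @param labels Binary vector.
#' @param binary_preds Binary prediction vector of equal length.
#' @return Named list: `tpr` (sensitivity), `fpr`, `specificity`; a rate
#'   with a zero denominator is returned as `NA` rather than raised.
#' @export
confusion_rates <- function(labels, binary_preds) {
  stopifnot(length(labels) == length(binary_preds),
            all(labels %in% c(0, 1)), all(binary_preds %in% c(0, 1)))
  tp <- sum(labels == 1 & binary_preds == 1)
  fn <- sum(labels == 1 & binary_preds == 0)
  fp <- sum(labels == 0 & binary_preds == 1)
  tn <- sum(labels == 0 & binary_preds == 0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  list(tpr = tpr, fpr = fpr,
       specificity = if (is.na(fpr)) NA_real_ else 1 - fpr)
}
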