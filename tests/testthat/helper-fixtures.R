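# Shared fixtures and independent oracles for the test suite.

# A single-lead record holding an arbitrary signal, for estimator tests.
signal_record <- function(x, fs = 500) {
  ecg_record(matrix(x, nrow = 1), fs = fs, source_id = "test-signal")
}

# The standard contamination bundle used throughout: strong sub-1 Hz wander
# (100x the clinical-band amplitude scale), a 50 Hz mains tone well above
# the noise background, and a halved overall amplitude.
contaminate_standard <- function(record) {
  out <- inject_baseline_wander(record, 0.3, 100)
  out <- inject_mains(out, 50, 1, 0.5)
  out$waveform <- out$waveform * 0.5
  out$contamination <- out$contamination * 0.5
  out
}

empty_peaks_df <- function() {
  data.frame(center_hz = numeric(0), lead = integer(0),
             lead_name = character(0), excess_sd = numeric(0),
             harmonic_of = numeric(0))
}

# Brute-force AUROC over all positive-negative pairs (ties: half credit).
auroc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Exhaustive balanced-accuracy threshold search (predict 1 when s >= t),
# scanning every unique score; returns the best achievable balanced
# accuracy and the set of optimal candidate thresholds.
balacc_bruteforce <- function(labels, scores) {
  cands <- sort(unique(scores))
  bal <- vapply(cands, function(t) {
    pred <- as.integer(scores >= t)
    sens <- sum(labels == 1 & pred == 1) / sum(labels == 1)
    spec <- sum(labels == 0 & pred == 0) / sum(labels == 0)
    (sens + spec) / 2
  }, numeric(1))
  list(best = max(bal), optimal = cands[bal == max(bal)])
}

balanced_accuracy_at <- function(labels, scores, threshold) {
  pred <- as.integer(scores >= threshold)
  sens <- sum(labels == 1 & pred == 1) / sum(labels == 1)
  spec <- sum(labels == 0 & pred == 0) / sum(labels == 0)
  (sens + spec) / 2
}

# Permutation test for a paired AUROC difference: labels fixed, the
# assignment of the two score columns to "model a" / "model b" is flipped
# per record, which preserves the pairing under the null.
delong_permutation_oracle <- function(labels, sa, sb, n_perm = 10000,
                                      seed = 1) {
  obs <- abs(auroc(labels, sa) - auroc(labels, sb))
  set.seed(seed)
  n <- length(labels)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    flip <- runif(n) < 0.5
    a <- ifelse(flip, sb, sa)
    b <- ifelse(flip, sa, sb)
    if (abs(auroc(labels, a) - auroc(labels, b)) >= obs - 1e-12)
      hits <- hits + 1L
  }
  hits / n_perm
}

# Two-group spec used by most fairness fixtures.
two_group_spec <- function(tpr_a = 0.9, tpr_b = 0.7, fpr = 0.1,
                           prevalence = 0.3) {
  data.frame(name = c("A", "B"), prevalence = prevalence,
             tpr = c(tpr_a, tpr_b), fpr = fpr)
}
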