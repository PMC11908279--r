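test_that("rank AUROC equals exhaustive pair counting, including ties", {
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_error(auroc(c(1, 1, 1), c(0.1, 0.2, 0.3)), "degenerate")

  set.seed(3)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), sample(1:3, 1))     # coarse rounding forces ties
    expect_identical(auroc(y, s), auroc_bruteforce(y, s))
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  for (i in 1:10) {
    y <- c(0, 1, rbinom(198, 1, 0.3))
    s <- runif(200)
    expect_equal(auroc(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("AUPRC behaves as an average-precision estimator", {
  expect_equal(auprc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  # hand-computed: ranks desc 0.9(+) 0.7(-) 0.5(+): AP = 1/2*(1 + 2/3)
  expect_equal(auprc(c(1, 0, 1), c(0.9, 0.7, 0.5)), (1 + 2 / 3) / 2)
  # random scores on a prevalence-pi set approach AP ~ pi
  set.seed(5)
  y <- rbinom(5000, 1, 0.3)
  expect_lt(abs(auprc(y, runif(5000)) - 0.3), 0.03)
})

test_that("overall AUROC concatenates labels and is column-order invariant", {
  ps1 <- generate_prediction_set(400, 1, two_group_spec(), rng_seed = 41)
  expect_equal(overall_auroc(ps1), auroc(ps1$labels[, 1], ps1$scores[, 1]))

  set.seed(6)
  n <- 500
  y1 <- rbinom(n, 1, 0.4); s1 <- ifelse(y1 == 1, runif(n, 0.5, 1), runif(n, 0, 0.5))
  y2 <- rbinom(n, 1, 0.4); s2 <- runif(n)
  ps <- prediction_set(cbind(s1, s2), cbind(y1, y2))
  ov <- overall_auroc(ps)
  expect_gt(ov, auroc(y2, s2))
  expect_lt(ov, auroc(y1, s1))
  flipped <- prediction_set(cbind(s2, s1), cbind(y2, y1))
  expect_equal(overall_auroc(flipped), ov)

  degen <- prediction_set(matrix(0.3, 4, 1), matrix(0, 4, 1))
  expect_error(overall_auroc(degen), "degenerate")
})

test_that("subsample CIs are deterministic, collapse for constants, and shrink with n", {
  ps <- generate_prediction_set(300, 1, two_group_spec(), rng_seed = 42)
  const <- bootstrap_metric(ps, function(p) 0.5, iterations = 50, seed = 1)
  expect_equal(const$ci_low, 0.5)
  expect_equal(const$ci_high, 0.5)

  ovm <- function(p) overall_auroc(p)
  a <- bootstrap_metric(ps, ovm, iterations = 200, seed = 9)
  b <- bootstrap_metric(ps, ovm, iterations = 200, seed = 9)
  expect_identical(a$values, b$values)
  expect_true(a$ci_low <= a$point && a$point <= a$ci_high)

  for (s in 1:3) {
    small <- generate_prediction_set(500, 1, two_group_spec(), rng_seed = 50 + s)
    big <- generate_prediction_set(5000, 1, two_group_spec(), rng_seed = 60 + s)
    ci_small <- bootstrap_metric(small, ovm, iterations = 200, seed = s)
    ci_big <- bootstrap_metric(big, ovm, iterations = 200, seed = s)
    expect_gt(ci_small$ci_high - ci_small$ci_low,
              ci_big$ci_high - ci_big$ci_low)
  }
})

test_that("DeLong test handles identity, symmetry, and matches references", {
  set.seed(7)
  y <- rbinom(200, 1, 0.4)
  s <- runif(200)
  same <- delong_test(y, s, s)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  sa <- ifelse(y == 1, pmin(1, s + 0.2), s)
  sb <- s
  ab <- delong_test(y, sa, sb)
  ba <- delong_test(y, sb, sa)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$auroc_a, ba$auroc_b)

  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE, direction = "<"),
                        pROC::roc(y, sb, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(ab$p_value, as.numeric(ref$p.value), tolerance = 1e-6)
})

test_that("threshold selection maximizes balanced accuracy exactly", {
  th <- select_thresholds(prediction_set(matrix(c(0.9, 0.6, 0.4, 0.1)),
                                         matrix(c(1, 1, 0, 0))))
  expect_gt(th, 0.4); expect_lte(th, 0.6)
  expect_equal(balanced_accuracy_at(c(1, 1, 0, 0), c(0.9, 0.6, 0.4, 0.1), th), 1)

  set.seed(8)
  for (i in 1:30) {
    n <- sample(20:300, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)
    got <- select_thresholds(prediction_set(matrix(s), matrix(y)))
    oracle <- balacc_bruteforce(y, s)
    expect_equal(balanced_accuracy_at(y, s, got), oracle$best)
  }

  # invariance under strictly monotone transforms of the scores
  y <- c(1, 1, 0, 1, 0, 0, 0, 1)
  s <- c(0.91, 0.63, 0.55, 0.52, 0.40, 0.22, 0.15, 0.70)
  th1 <- select_thresholds(prediction_set(matrix(s), matrix(y)))
  s2 <- s^3
  th2 <- select_thresholds(prediction_set(matrix(s2), matrix(y)))
  expect_equal(balanced_accuracy_at(y, s, th1),
               balanced_accuracy_at(y, s2, th2))

  expect_warning(th <- select_thresholds(prediction_set(
    cbind(a = c(0.2, 0.8), b = c(0.3, 0.4)),
    cbind(a = c(0, 1), b = c(1, 1)))), "degenerate")
  expect_true(is.na(th[["b"]]))
  expect_false(is.na(th[["a"]]))
})

test_that("confusion rates count exactly and encode undefined cases", {
  y <- c(rep(1, 10), rep(0, 10))
  expect_equal(confusion_rates(y, y), list(tpr = 1, fpr = 0, specificity = 1))
  expect_equal(confusion_rates(y, 1 - y),
               list(tpr = 0, fpr = 1, specificity = 0))

  # TP=8 FN=2 FP=1 TN=9
  pred <- c(rep(1, 8), rep(0, 2), 1, rep(0, 9))
  cr <- confusion_rates(y, pred)
  expect_equal(cr$tpr, 0.8)
  expect_equal(cr$fpr, 0.1)

  expect_true(is.na(confusion_rates(rep(0, 5), rep(0, 5))$tpr))
})
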