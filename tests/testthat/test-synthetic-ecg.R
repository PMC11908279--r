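test_that("generator is deterministic and honors degenerate configs", {
  cfg <- synth_config(rng_seed = 7)
  expect_identical(generate_record(cfg)$waveform, generate_record(cfg)$waveform)

  zero_bumps <- default_beat_params()
  zero_bumps$amplitude_mv <- 0
  silent <- synth_config(beat_params = zero_bumps, noise_sd = 0, rng_seed = 1)
  expect_true(all(generate_record(silent)$waveform == 0))

  expect_error(synth_config(fs = -1), "fs")
  expect_error(synth_config(duration_s = 0), "duration")
  bad <- default_beat_params(); bad$amplitude_mv[1] <- Inf
  expect_error(synth_config(beat_params = bad), "finite")
})

test_that("beat train is periodic at the configured heart rate", {
  cfg <- synth_config(heart_rate_bpm = 60, duration_s = 10, n_leads = 1,
                      noise_sd = 0.01, rng_seed = 2)
  rec <- generate_record(cfg)
  x <- rec$waveform[1, ] - mean(rec$waveform[1, ])
  ac <- stats::acf(x, lag.max = 600, plot = FALSE)$acf[-1]
  # autocorrelation must peak at one beat period = fs samples (1 s at 60 bpm)
  expect_equal(which.max(ac[400:600]) + 399, 500, tolerance = 0.01)
  expect_gt(ac[500], 0.8)
})

test_that("baseline wander injection is additive, sub-1 Hz only, and exact", {
  rec <- generate_record(synth_config(rng_seed = 3))
  expect_error(inject_baseline_wander(rec, 1.0, 1), "\\(0, 1\\)")
  expect_error(inject_baseline_wander(rec, 2.5, 1), "\\(0, 1\\)")

  same <- inject_baseline_wander(rec, 0.3, 0)
  expect_equal(same$waveform, rec$waveform)

  A <- 2
  cont <- inject_baseline_wander(rec, 0.3, A)
  expect_equal(rec$waveform, cont$waveform - cont$contamination,
               tolerance = 1e-12)
  # Parseval: integrated power gained near 0.3 Hz matches the sinusoid's
  # A^2/2. Full-record resolution (0.1 Hz) puts 0.3 Hz on-grid, so the
  # only slack needed is residual leakage from windowing.
  gain_band <- function(r) {
    sp <- power_spectrum(r, segment_s = record_duration(r))
    idx <- which(sp$freqs > 0 & sp$freqs <= 0.8)
    mean(rowSums(sp$power[, idx, drop = FALSE])) * (sp$freqs[2] - sp$freqs[1])
  }
  expect_equal(gain_band(cont) - gain_band(rec), A^2 / 2, tolerance = 0.1)

  both <- inject_baseline_wander(inject_baseline_wander(rec, 0.2, 3), 0.4, 3)
  sp <- power_spectrum(both, segment_s = 5)
  pooled <- colMeans(sp$power)
  i02 <- which.min(abs(sp$freqs - 0.2)); i04 <- which.min(abs(sp$freqs - 0.4))
  base <- median(pooled[sp$freqs > 2 & sp$freqs < 10])
  expect_gt(pooled[i02], 100 * base)
  expect_gt(pooled[i04], 100 * base)
})

test_that("mains injection places tones at the requested harmonics", {
  rec <- generate_record(synth_config(rng_seed = 4))
  expect_error(inject_mains(rec, 60, 5, 0.1), "Nyquist")
  expect_equal(inject_mains(rec, 50, 1, 0)$waveform, rec$waveform)

  cont <- inject_mains(rec, 60, 3, c(0.5, 0.3, 0.2))
  expect_equal(cont$meta$contaminated_hz, c(60, 120, 180))
  sp <- power_spectrum(cont, segment_s = 2)
  pooled <- colMeans(sp$power)
  for (fc in c(60, 120, 180)) {
    near <- which.min(abs(sp$freqs - fc))
    bg <- median(pooled[abs(sp$freqs - fc) > 2 & abs(sp$freqs - fc) < 10])
    expect_gt(pooled[near], 50 * bg)
  }
  expect_equal(rec$waveform, cont$waveform - cont$contamination,
               tolerance = 1e-12)
})

test_that("prediction-set generator reproduces designed rates at scale", {
  expect_error(generate_prediction_set(100, 2,
                                       two_group_spec(tpr_a = 1.2)), "\\[0, 1\\]")

  # identical targets: measured disparity shrinks to MC noise
  ps0 <- generate_prediction_set(20000, 2, two_group_spec(0.8, 0.8),
                                 rng_seed = 5)
  th <- rep(0.5, 2)
  gr <- group_rates(ps0, th, "sex")
  expect_lt(abs(diff(gr$tpr)), 0.02)

  # designed 0.2 TPR gap recovered by direct counting
  ps <- generate_prediction_set(20000, 2, two_group_spec(0.9, 0.7),
                                rng_seed = 6)
  gr <- group_rates(ps, th, "sex")
  expect_lt(abs(gr$tpr[gr$group == "A"] - 0.9), 0.02)
  expect_lt(abs(gr$tpr[gr$group == "B"] - 0.7), 0.02)
  expect_lt(abs(abs(diff(gr$tpr)) - 0.2), 0.02)

  # zero prevalence: no positives at all
  none <- generate_prediction_set(500, 1,
                                  data.frame(name = "A", prevalence = 0,
                                             tpr = 0.9, fpr = 0.1),
                                  rng_seed = 7)
  expect_equal(sum(none$labels), 0)

  # empirical convergence at n = 50,000 within 0.01 (single group)
  big <- generate_prediction_set(50000, 1,
                                 data.frame(name = "A", prevalence = 0.4,
                                            tpr = 0.85, fpr = 0.15),
                                 rng_seed = 8)
  pred <- as.integer(big$scores[, 1] >= 0.5)
  cr <- confusion_rates(big$labels[, 1], pred)
  expect_lt(abs(cr$tpr - 0.85), 0.01)
  expect_lt(abs(cr$fpr - 0.15), 0.01)
  expect_lt(abs(mean(big$labels) - 0.4), 0.01)
})

test_that("logit-set generator controls the train/held-out shift", {
  expect_error(generate_logit_sets(0, 10, 3), "positive")

  ls1 <- generate_logit_sets(200, 200, 4, rng_seed = 9)
  ls2 <- generate_logit_sets(200, 200, 4, rng_seed = 9)
  expect_identical(ls1, ls2)

  null_sets <- generate_logit_sets(2000, 2000, 4, shift = 0, rng_seed = 10)
  expect_lt(abs(mean(null_sets$test) - mean(null_sets$train)), 0.05)

  # a 10 SD shift on one feature makes the sets separable on that feature
  sep <- generate_logit_sets(1000, 1000, 4, shift = c(10, 0, 0, 0),
                             rng_seed = 11)
  expect_gt(min(sep$test[, 1]), max(sep$train[, 1]))
})
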