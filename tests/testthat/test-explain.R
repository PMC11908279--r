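# A small record keeps perturbation loops fast without changing the logic.
lime_fixture_record <- function(seed = 1) {
  generate_record(synth_config(fs = 100, duration_s = 10, n_leads = 2,
                               rng_seed = seed))
}

test_that("segmentation tiles the signal with the remainder in the last span", {
  rec <- generate_record(synth_config(fs = 500, duration_s = 10, n_leads = 1,
                                      rng_seed = 1))
  segs <- segment_signal(rec, 10)
  expect_equal(nrow(segs), 10)
  expect_true(all(segs$end - segs$start == 500))

  odd <- signal_record(rnorm(5001))
  segs2 <- segment_signal(odd, 10)
  expect_equal(segs2$end[10] - segs2$start[10], 501)

  # tiling: spans cover every sample exactly once per lead
  rec2 <- lime_fixture_record()
  segs3 <- segment_signal(rec2, 7)
  for (ld in 1:2) {
    covered <- unlist(mapply(function(a, b) seq(a, b - 1),
                             segs3$start[segs3$lead == ld],
                             segs3$end[segs3$lead == ld]))
    expect_identical(sort(covered), 0:999)
  }
  expect_error(segment_signal(rec2, 0), "positive")
  expect_error(segment_signal(rec2, 5000), "segments")
})

test_that("constant scoring functions yield zero attribution, flagged", {
  rec <- lime_fixture_record()
  att <- lime_attribute(function(r) c(yes = 0.7), rec, "yes",
                        n_segments = 5, n_perturbations = 64, seed = 1)
  expect_true(all(att$segments$weight == 0))
  expect_true(is.na(att$r_squared))
})

test_that("a linear oracle's active segment receives the top weight", {
  rec <- lime_fixture_record(2)
  segs <- segment_signal(rec, 10)
  target <- which(segs$lead == 1 & segs$segment == 3)
  score_fn <- function(r) {
    i <- (segs$start[target] + 1):segs$end[target]
    c(lbl = mean(r$waveform[1, i]))
  }
  hits <- 0L
  for (s in 1:20) {
    att <- lime_attribute(score_fn, rec, "lbl", n_segments = 10,
                          n_perturbations = 300, seed = s)
    if (which.max(att$segments$weight) == target) hits <- hits + 1L
  }
  expect_gte(hits, 19L)   # >= 95% recovery
})

test_that("segments on an ignored lead stay inside the noise band", {
  rec <- lime_fixture_record(3)
  segs <- segment_signal(rec, 10)
  score_fn <- function(r) c(lbl = mean(r$waveform[1, ]))  # lead 2 unused
  att <- lime_attribute(score_fn, rec, "lbl", n_segments = 10,
                        n_perturbations = 500, seed = 4)
  w <- att$segments$weight
  lead2 <- att$segments$lead == 2
  expect_lt(max(abs(w[lead2])), 0.05 * max(abs(w)))
})

test_that("attribution for one label ignores all other label outputs", {
  rec <- lime_fixture_record(4)
  base_fn <- function(r) c(a = mean(r$waveform[1, 1:100]),
                           b = mean(r$waveform[2, ]))
  perm_fn <- function(r) { v <- base_fn(r); v[["b"]] <- -3 * v[["b"]] + 1; v }
  att1 <- lime_attribute(base_fn, rec, "a", n_segments = 8,
                         n_perturbations = 200, seed = 5)
  att2 <- lime_attribute(perm_fn, rec, "a", n_segments = 8,
                         n_perturbations = 200, seed = 5)
  expect_identical(att1$segments$weight, att2$segments$weight)
})

test_that("attributions are seed-deterministic and stabilize with sampling", {
  rec <- lime_fixture_record(5)
  segs <- segment_signal(rec, 10)
  set.seed(6)
  coef_true <- rnorm(nrow(segs))
  score_fn <- function(r) {
    means <- vapply(seq_len(nrow(segs)), function(k)
      mean(r$waveform[segs$lead[k], (segs$start[k] + 1):segs$end[k]]),
      numeric(1))
    c(lbl = sum(coef_true * means))
  }
  a <- lime_attribute(score_fn, rec, "lbl", n_segments = 10,
                      n_perturbations = 200, seed = 7)
  b <- lime_attribute(score_fn, rec, "lbl", n_segments = 10,
                      n_perturbations = 200, seed = 7)
  expect_identical(a$segments$weight, b$segments$weight)

  # faithfulness: recovered weights track the true linear coefficients
  # (true surrogate coefficient for segment k is coef_true_k * segment mean)
  seg_means <- vapply(seq_len(nrow(segs)), function(k)
    mean(rec$waveform[segs$lead[k], (segs$start[k] + 1):segs$end[k]]),
    numeric(1))
  truth <- coef_true * seg_means
  rho <- cor(a$segments$weight, truth, method = "spearman")
  expect_gt(rho, 0.9)
  expect_gt(a$r_squared, 0.99)

  # variance shrinks as the perturbation budget grows
  spread <- function(np) {
    ws <- sapply(1:5, function(s)
      lime_attribute(score_fn, rec, "lbl", n_segments = 10,
                     n_perturbations = np, seed = 10 + s)$segments$weight)
    mean(apply(ws, 1, sd))
  }
  expect_lt(spread(400), spread(50))
})
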