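test_that("zero-phase high-pass attenuates drift and preserves the band", {
  fs <- 500; t <- (0:4999) / fs
  slow <- signal_record(sin(2 * pi * 0.3 * t), fs)
  hp <- apply_highpass(slow, cutoff_hz = 1)
  # >= 20 dB power attenuation at 0.3 Hz (designed response is far steeper)
  expect_lt(var(hp$waveform[1, ]) / var(slow$waveform[1, ]), 0.01)

  fast <- signal_record(sin(2 * pi * 10 * t), fs)
  hf <- apply_highpass(fast, cutoff_hz = 1)
  mid <- 1000:4000  # interior, away from any residual edge effect
  expect_equal(sd(hf$waveform[1, mid]) / sd(fast$waveform[1, mid]), 1,
               tolerance = 0.01)
  # zero phase: no shift of the waveform
  expect_gt(cor(hf$waveform[1, mid], fast$waveform[1, mid]), 0.9999)

  zero <- signal_record(rep(0, 5000))
  expect_true(all(apply_highpass(zero)$waveform == 0))
  expect_error(apply_highpass(fast, cutoff_hz = 300), "Nyquist")
})

test_that("flattening removes peaks locally and spares the clean signal", {
  rec <- generate_record(synth_config(rng_seed = 21))
  expect_identical(flatten_peaks(rec, empty_peaks_df()), rec)

  tone <- inject_mains(rec, 50, 1, 0.5)
  sp <- power_spectrum(tone, segment_s = 2)
  pk <- detect_artifact_peaks(sp)
  expect_gt(nrow(pk), 0)
  flat <- flatten_peaks(tone, pk)
  # re-running the detector is the oracle: nothing left to find
  expect_equal(nrow(detect_artifact_peaks(power_spectrum(flat, segment_s = 2))), 0)
  # distortion of the underlying clean signal stays below 5% RMS
  rms <- function(m) sqrt(mean(m^2))
  expect_lt(rms(flat$waveform - rec$waveform), 0.05 * rms(rec$waveform))

  dc_peak <- pk; dc_peak$center_hz <- 0.5
  expect_error(flatten_peaks(tone, dc_peak), "DC")
  nyq_peak <- pk; nyq_peak$center_hz <- 249.9
  expect_error(flatten_peaks(tone, nyq_peak), "Nyquist")
})

test_that("reference profiles pool records and scale equivariantly", {
  recs <- lapply(31:33, function(s) generate_record(synth_config(rng_seed = s)))
  prof <- build_reference_profile(recs)

  doubled <- lapply(recs, function(r) { r$waveform <- 2 * r$waveform; r })
  prof2 <- build_reference_profile(doubled)
  expect_equal(prof2$p_high - prof2$p_low, 2 * (prof$p_high - prof$p_low),
               tolerance = 1e-10)

  one <- build_reference_profile(recs[[1]])
  dup <- build_reference_profile(list(recs[[1]], recs[[1]]))
  expect_equal(dup$p_low, one$p_low)
  expect_equal(dup$p_high, one$p_high)

  const <- signal_record(rep(3, 1000))
  expect_error(build_reference_profile(const), "degenerate")
  short <- generate_record(synth_config(n_leads = 3, rng_seed = 1))
  expect_error(build_reference_profile(list(recs[[1]], short)), "inconsistent")
})

test_that("amplitude matching is a projection onto the reference range", {
  rec <- generate_record(synth_config(rng_seed = 34))
  ref <- build_reference_profile(rec)

  fixed <- amplitude_match(rec, ref)
  expect_equal(attr(fixed, "scale_factors"), rep(1, 12), tolerance = 1e-10)

  half <- rec; half$waveform <- rec$waveform * 0.5
  m <- amplitude_match(half, ref)
  expect_equal(attr(m, "scale_factors"), rep(2, 12), tolerance = 1e-10)
  # shape preserved exactly
  expect_equal(cor(m$waveform[1, ], half$waveform[1, ]), 1)

  twice <- amplitude_match(m, ref)
  expect_equal(m$waveform, twice$waveform, tolerance = 1e-10)

  # scale equivariance: match(c x) == match(x)
  thrice <- rec; thrice$waveform <- rec$waveform * 37
  expect_equal(amplitude_match(thrice, ref)$waveform,
               amplitude_match(rec, ref)$waveform, tolerance = 1e-8)

  flatlead <- rec; flatlead$waveform[3, ] <- 0
  expect_warning(out <- amplitude_match(flatlead, ref), "zero-span")
  expect_equal(attr(out, "scale_factors")[3], 1)
})

test_that("full pipeline is a conditional no-op on conforming records", {
  rec <- generate_record(synth_config(rng_seed = 35))
  ref <- build_reference_profile(rec)
  res <- harmonize_record(rec, ref)
  expect_equal(sum(res$log$highpass_applied), 0)
  expect_equal(nrow(res$log$peaks_removed), 0)
  expect_equal(res$log$scale_factors, rep(1, 12), tolerance = 1e-10)
  expect_equal(res$record$waveform, rec$waveform, tolerance = 1e-8)
})

test_that("full pipeline fires all stages on the standard contamination and converges", {
  rec <- generate_record(synth_config(rng_seed = 36))
  cont <- contaminate_standard(rec)
  ref <- build_reference_profile(rec)
  res <- harmonize_record(cont, ref)
  cfg <- res$log$config

  expect_equal(sum(res$log$highpass_applied), 12)
  expect_true(50 %in% res$log$peaks_removed$center_hz)
  expect_true(all(res$log$scale_factors > 1.5))

  out <- res$record
  expect_true(all(lowfreq_excess(power_spectrum(out, cfg$segment_s_lowfreq)) <= 1))
  expect_equal(nrow(detect_artifact_peaks(power_spectrum(out, cfg$segment_s))), 0)

  # second pass: all triggers false (idempotence of the decision rules)
  res2 <- harmonize_record(out, ref)
  expect_equal(sum(res2$log$highpass_applied), 0)
  expect_equal(nrow(res2$log$peaks_removed), 0)
  expect_equal(res2$log$scale_factors, rep(1, 12), tolerance = 1e-6)
})

test_that("the decision log replays the transform bit-exactly", {
  rec <- generate_record(synth_config(rng_seed = 37))
  cont <- contaminate_standard(rec)
  res <- harmonize_record(cont, build_reference_profile(rec))
  replayed <- replay_harmonization(cont, res$log)
  expect_identical(replayed$waveform, res$record$waveform)

  # ... including after a JSON round trip of the log
  path <- tempfile(fileext = ".json")
  write_harmonization_log(res$log, path)
  log2 <- read_harmonization_log(path)
  # JSON decimal round-trip costs at most 1 ulp on the scale factors
  expect_equal(replay_harmonization(cont, log2)$waveform,
               res$record$waveform, tolerance = 1e-12)
})
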