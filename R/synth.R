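#' Configuration for the synthetic ECG generator
#'
#' The pseudo-ECG is a quasi-periodic train of Gaussian bumps — one bump per
#' deflection (P, Q, R, S, T) per beat — which reproduces the spectral band
#' occupancy of real ECG (energy concentrated in roughly 1-30 Hz) without
#' attempting physiological fidelity. That is all the harmonization pipeline
#' depends on, and it makes every contamination exactly known.
#'
#' `beat_params` places each bump at `offset_frac` of the beat-to-beat
#' interval relative to the R-wave center, with a Gaussian width in seconds
#' and a signed amplitude in millivolts. The defaults approximate a normal
#' sinus beat: a small P wave before the complex, a narrow tall R with
#' flanking Q/S troughs, and a broad T wave after it.
#'
#' @param fs Sampling rate, Hz (default 500).
#' @param duration_s Record length, seconds (default 10, the standard
#'   clinical strip).
#' @param n_leads Number of leads (default 12).
#' @param heart_rate_bpm Heart rate, beats per minute (default 72, a
#'   typical resting rate; it also keeps the beat fundamental away from
#'   both the 1 Hz high-pass cutoff and the sub-1 Hz trigger band, a
#'   degenerate alignment no real recording would lock into).
#' @param beat_params Data frame with columns `wave`, `offset_frac`,
#'   `width_s`, `amplitude_mv`.
#' @param lead_scale_range Per-lead amplitude multipliers are drawn
#'   uniformly from this range (length-2 vector), emulating between-lead and
#'   between-dataset gain differences.
#' @param noise_sd Additive white measurement noise, mV (default 0.02).
#' @param rng_seed Integer seed; fixes lead scales and noise.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(fs = 500, duration_s = 10, n_leads = 12,
                         heart_rate_bpm = 72,
                         beat_params = default_beat_params(),
                         lead_scale_range = c(0.6, 1.4),
                         noise_sd = 0.02, rng_seed = NULL) {
  if (!is.numeric(fs) || fs <= 0) stop_ecg("`fs` must be a positive Hz value")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop_ecg("`duration_s` must be positive")
  if (n_leads < 1) stop_ecg("`n_leads` must be >= 1")
  if (heart_rate_bpm <= 0) stop_ecg("`heart_rate_bpm` must be positive")
  stopifnot(is.data.frame(beat_params),
            all(c("wave", "offset_frac", "width_s", "amplitude_mv") %in%
                  names(beat_params)))
  if (any(!is.finite(beat_params$amplitude_mv)))
    stop_ecg("bump amplitudes must be finite")
  if (any(beat_params$width_s <= 0)) stop_ecg("bump widths must be positive")
  structure(list(fs = fs, duration_s = duration_s, n_leads = n_leads,
                 heart_rate_bpm = heart_rate_bpm, beat_params = beat_params,
                 lead_scale_range = lead_scale_range, noise_sd = noise_sd,
                 rng_seed = rng_seed),
            class = "synth_config")
}

#' Default P-QRS-T bump parameters
#'
#' Offsets are fractions of the beat-to-beat interval relative to the R
#' center; widths are Gaussian sigmas in seconds; amplitudes in mV.
#' @return A data frame with one row per deflection.
#' @export
default_beat_params <- function() {
  data.frame(
    wave         = c("P", "Q", "R", "S", "T"),
    offset_frac  = c(-0.18, -0.035, 0.00, 0.035, 0.28),
    width_s      = c(0.040, 0.010, 0.012, 0.010, 0.060),
    amplitude_mv = c(0.15, -0.12, 1.00, -0.25, 0.35)
  )
}

#' Generate a clean synthetic ECG record
#'
#' Deterministic under `config$rng_seed`: the per-lead gain multipliers and
#' the white measurement noise are the only random components. The noiseless
#' clean waveform is stored in `meta$clean` as an oracle, and
#' `contamination` starts at zero.
#'
#' @param config A [synth_config()].
#' @return An [ecg_record()].
#' @export
generate_record <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n <- round(fs * config$duration_s)
  t <- (seq_len(n) - 1) / fs
  period <- 60 / config$heart_rate_bpm
  centers <- seq(period / 2, config$duration_s, by = period)
  base <- numeric(n)
  bp <- config$beat_params
  for (tc in centers) {
    for (k in seq_len(nrow(bp))) {
      mu <- tc + bp$offset_frac[k] * period
      base <- base + bp$amplitude_mv[k] *
        exp(-((t - mu)^2) / (2 * bp$width_s[k]^2))
    }
  }
  with_seed(config$rng_seed, {
    scales <- runif(config$n_leads, config$lead_scale_range[1],
                    config$lead_scale_range[2])
    wv <- outer(scales, base)
    if (config$noise_sd > 0)
      wv <- wv + matrix(rnorm(length(wv), sd = config$noise_sd),
                        nrow = config$n_leads)
    ecg_record(wv, fs = fs, source_id = "synthetic",
               contamination = matrix(0, config$n_leads, n),
               meta = list(clean = wv, lead_scales = scales,
                           heart_rate_bpm = config$heart_rate_bpm,
                           injections = list()))
  })
}

inject_additive <- function(record, trace_row, log_entry) {
  wv <- record$waveform
  trace <- matrix(rep(trace_row, each = nrow(wv)), nrow = nrow(wv))
  out <- record
  out$waveform <- wv + trace
  out$contamination <- (record$contamination %||%
                          matrix(0, nrow(wv), ncol(wv))) + trace
  out$meta$injections <- c(record$meta$injections %||% list(), list(log_entry))
  out
}

#' Inject sub-1 Hz baseline wander
#'
#' Adds the same sinusoid, `amplitude_mv * sin(2 pi f t + phase)`, to every
#' lead. Wander is by definition sub-1 Hz here (respiration / patient
#' movement), so `freq_hz >= 1` is an error. The added trace is accumulated
#' in the record's `contamination` matrix, so the injection is exactly
#' invertible.
#'
#' @param record An [ecg_record()].
#' @param freq_hz Wander frequency in (0, 1) Hz.
#' @param amplitude_mv Amplitude, mV.
#' @param phase Radians (default 0).
#' @return A new contaminated `ecg_record`; the input is not modified.
#' @export
inject_baseline_wander <- function(record, freq_hz, amplitude_mv, phase = 0) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.numeric(freq_hz) || freq_hz <= 0 || freq_hz >= 1)
    stop_ecg("baseline wander frequency must lie in (0, 1) Hz, got %g", freq_hz)
  t <- (seq_len(n_samples(record)) - 1) / record$fs
  trace <- amplitude_mv * sin(2 * pi * freq_hz * t + phase)
  inject_additive(record, trace,
                  list(type = "baseline_wander", freq_hz = freq_hz,
                       amplitude_mv = amplitude_mv, phase = phase))
}

#' Inject mains (powerline) interference with harmonics
#'
#' Adds tones at `base_hz, 2*base_hz, ..., n_harmonics*base_hz` on every
#' lead. Each contaminated frequency is recorded in
#' `meta$contaminated_hz` so detector tests have an exact oracle.
#'
#' @param record An [ecg_record()].
#' @param base_hz Mains frequency, typically 50 or 60 Hz.
#' @param n_harmonics Number of tones including the fundamental.
#' @param amplitudes_mv Amplitude per tone (recycled to `n_harmonics`).
#' @param phase Radians (default 0), recycled.
#' @return A new contaminated `ecg_record`.
#' @export
inject_mains <- function(record, base_hz = 50, n_harmonics = 1,
                         amplitudes_mv = 0.1, phase = 0) {
  stopifnot(inherits(record, "ecg_record"))
  if (base_hz <= 0) stop_ecg("`base_hz` must be positive")
  nyq <- record$fs / 2
  if (base_hz * n_harmonics >= nyq)
    stop_ecg("harmonic %g Hz is at or above Nyquist (%g Hz)",
             base_hz * n_harmonics, nyq)
  amplitudes_mv <- rep_len(amplitudes_mv, n_harmonics)
  phase <- rep_len(phase, n_harmonics)
  t <- (seq_len(n_samples(record)) - 1) / record$fs
  trace <- numeric(length(t))
  for (h in seq_len(n_harmonics))
    trace <- trace + amplitudes_mv[h] * sin(2 * pi * h * base_hz * t + phase[h])
  out <- inject_additive(record, trace,
                         list(type = "mains", base_hz = base_hz,
                              n_harmonics = n_harmonics,
                              amplitudes_mv = amplitudes_mv))
  out$meta$contaminated_hz <- sort(unique(c(out$meta$contaminated_hz %||% numeric(0),
                                            base_hz * seq_len(n_harmonics))))
  out
}

#' Generate a multilabel prediction set with designed group-wise rates
#'
#' Draws, for every record x label cell, a binary outcome at the group's
#' prevalence and then a score from one of two fixed Beta-shaped
#' distributions straddling 0.5: positives score above 0.5 with probability
#' equal to the group's target TPR, negatives with probability equal to the
#' target FPR. Thresholding at 0.5 therefore reproduces the designed
#' confusion rates exactly in expectation, and empirical rates converge to
#' the targets by the law of large numbers.
#'
#' @param n_records Number of records.
#' @param n_labels Number of labels (same targets applied to each label).
#' @param group_spec Data frame with columns `name`, `prevalence`, `tpr`,
#'   `fpr` and optionally `fraction` (group weights, default equal).
#' @param rng_seed Integer seed.
#' @param assign_to `"sex"` (group name stored as sex, ages uniform 30-90)
#'   or `"age"` (groups mapped onto the under-55 / 55-75 / over-75 bins).
#' @return A [prediction_set()] with `group` set to the design group.
#' @export
generate_prediction_set <- function(n_records, n_labels, group_spec,
                                    rng_seed = NULL, assign_to = c("sex", "age")) {
  assign_to <- match.arg(assign_to)
  stopifnot(is.data.frame(group_spec),
            all(c("name", "prevalence", "tpr", "fpr") %in% names(group_spec)))
  rates <- as.matrix(group_spec[, c("prevalence", "tpr", "fpr")])
  if (anyNA(rates) || any(rates < 0 | rates > 1))
    stop_ecg("prevalence/tpr/fpr targets must all lie in [0, 1]")
  G <- nrow(group_spec)
  frac <- group_spec$fraction %||% rep(1 / G, G)
  if (any(frac <= 0)) stop_ecg("group fractions must be positive")
  frac <- frac / sum(frac)
  if (assign_to == "age" && G > 3)
    stop_ecg("at most 3 groups can be mapped onto the age bins")
  with_seed(rng_seed, {
    g <- sample.int(G, n_records, replace = TRUE, prob = frac)
    ncell <- n_records * n_labels
    prev <- group_spec$prevalence[g]
    y <- matrix(rbinom(ncell, 1, rep(prev, n_labels)), nrow = n_records)
    p_hi <- ifelse(y == 1, group_spec$tpr[g], group_spec$fpr[g])
    hi <- matrix(rbinom(ncell, 1, p_hi), nrow = n_records)
    mag <- matrix(rbeta(ncell, 2, 2), nrow = n_records)
    s <- ifelse(hi == 1, 0.5 + 0.5 * mag, 0.5 - 0.5 * mag)
    if (assign_to == "sex") {
      sex <- as.character(group_spec$name[g])
      age <- runif(n_records, 30, 90)
    } else {
      bins <- list(c(30, 54.5), c(55, 75), c(75.5, 95))
      sex <- sample(c("F", "M"), n_records, replace = TRUE)
      age <- vapply(g, function(gi) runif(1, bins[[gi]][1], bins[[gi]][2]),
                    numeric(1))
    }
    prediction_set(s, y, age = age, sex = sex,
                   group = as.character(group_spec$name[g]))
  })
}

#' Generate train/held-out logit sets with a controllable shift
#'
#' Both sets are drawn from independent multivariate standard Gaussians; the
#' held-out set's feature means are offset by `shift`. `shift = 0` makes the
#' two sets exchangeable, the null for any membership-inference attack.
#'
#' @param n_train,n_test Row counts.
#' @param n_features Feature (logit) dimension.
#' @param shift Scalar or length-`n_features` per-feature mean offset for
#'   the held-out set, in SD units.
#' @param rng_seed Integer seed.
#' @return List with `train` and `test` numeric matrices.
#' @export
generate_logit_sets <- function(n_train, n_test, n_features, shift = 0,
                                rng_seed = NULL) {
  if (n_train <= 0 || n_test <= 0 || n_features <= 0)
    stop_ecg("set sizes and feature count must be positive")
  shift <- rep_len(shift, n_features)
  with_seed(rng_seed, {
    tr <- matrix(rnorm(n_train * n_features), nrow = n_train)
    te <- matrix(rnorm(n_test * n_features), nrow = n_test)
    te <- sweep(te, 2, shift, "+")
    colnames(tr) <- colnames(te) <- paste0("logit", seq_len(n_features))
    list(train = tr, test = te)
  })
}
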