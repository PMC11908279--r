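#' Per-lead Welch power spectral density
#'
#' Averaged-periodogram (Welch) estimate with a Hann window: the record is
#' split into `segment_s`-second segments overlapping by `overlap_frac`,
#' each segment is windowed and its periodogram computed, and the
#' periodograms are averaged per lead. Frequency resolution is
#' `1/segment_s`. Power is a one-sided density (mV^2/Hz), so summing
#' `power * df` over all bins recovers the time-domain mean square within
#' leakage tolerance (Parseval).
#'
#' @param record An [ecg_record()].
#' @param segment_s Segment length, seconds (default 2, giving 0.5 Hz
#'   resolution on a 10 s record).
#' @param overlap_frac Segment overlap fraction in `[0, 1)` (default 0.5).
#' @return An object of class `power_spectrum`: `freqs` (Hz, ascending from
#'   0 to Nyquist) and `power` (`n_leads x n_freqs` matrix).
#' @export
power_spectrum <- function(record, segment_s = 2, overlap_frac = 0.5) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  n <- n_samples(record)
  nseg <- round(segment_s * fs)
  if (nseg > n)
    stop_ecg("segment_s (%g s) exceeds record duration (%g s)",
             segment_s, n / fs)
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop_ecg("`overlap_frac` must lie in [0, 1)")
  step <- max(1L, round(nseg * (1 - overlap_frac)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1) / nseg))  # periodic Hann
  U <- sum(w^2)                                              # window power
  n_freq <- nseg %/% 2 + 1
  freqs <- (seq_len(n_freq) - 1) * fs / nseg
  pow <- matrix(0, n_leads(record), n_freq)
  for (s0 in starts) {
    seg <- record$waveform[, s0:(s0 + nseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)            # detrend each segment (constant)
    seg <- sweep(seg, 2, w, "*")
    X <- t(apply(seg, 1, fft))
    if (n_leads(record) == 1L) X <- matrix(X, nrow = 1)
    P <- (Mod(X[, seq_len(n_freq), drop = FALSE])^2) / (fs * U)
    P[, -c(1L, if (nseg %% 2 == 0) n_freq)] <-
      2 * P[, -c(1L, if (nseg %% 2 == 0) n_freq)]            # one-sided
    pow <- pow + P
  }
  pow <- pow / length(starts)
  structure(list(freqs = freqs, power = pow, fs = fs,
                 segment_s = segment_s, overlap_frac = overlap_frac,
                 n_segments = length(starts),
                 lead_names = record$lead_names),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d lead(s), %d bins, df=%g Hz (Welch, %d segments)\n",
              nrow(x$power), length(x$freqs), x$freqs[2] - x$freqs[1],
              x$n_segments))
  invisible(x)
}

log10_floor <- function(p) log10(pmax(p, 1e-300))

#' Sub-1 Hz log-power excess (high-pass trigger)
#'
#' Per lead, the mean log10 power over (0, 1) Hz minus the mean log10 power
#' over [1, 30] Hz. Values above 1 — one logarithmic unit of low-frequency
#' enrichment, the signature of baseline wander — trigger the 1 Hz
#' high-pass stage. The log-ratio is invariant to global amplitude scaling.
#'
#' @param spectrum A [power_spectrum()] whose frequencies cover `[0, 30]` Hz.
#' @param low_band,ref_band Band edges, Hz. The low band is open at both
#'   ends (DC excluded); the reference band is closed.
#' @return Named numeric vector, one excess value per lead.
#' @export
lowfreq_excess <- function(spectrum, low_band = c(0, 1), ref_band = c(1, 30)) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  f <- spectrum$freqs
  if (max(f) < ref_band[2])
    stop_ecg("spectrum reaches only %g Hz; need coverage to %g Hz",
             max(f), ref_band[2])
  i_low <- which(f > low_band[1] & f < low_band[2])
  i_ref <- which(f >= ref_band[1] & f <= ref_band[2])
  if (!length(i_low))
    stop_ecg(paste0("no frequency bins inside (%g, %g) Hz at resolution %g Hz; ",
                    "increase segment_s"), low_band[1], low_band[2], f[2] - f[1])
  lp <- log10_floor(spectrum$power)
  out <- rowMeans(lp[, i_low, drop = FALSE]) -
    rowMeans(lp[, i_ref, drop = FALSE])
  names(out) <- spectrum$lead_names
  out
}

#' Detect mains artifact peaks by the local 2-SD rule
#'
#' For each candidate base frequency (50 and 60 Hz by default) and each
#' harmonic below Nyquist, the detector compares the candidate's log10
#' power against the local spectral baseline: the mean and SD of per-bin
#' log10 power inside a `+/- local_window_hz` window around the candidate,
#' excluding a `+/- exclusion_hz` zone at the candidate itself (so a peak
#' cannot inflate its own baseline). The candidate statistic is the mean
#' log10 power over the exclusion-zone bins — the bins a windowed tone's
#' energy actually occupies — and a peak is emitted when it exceeds
#' `local mean + k_sd * local SD`. Harmonics above the fundamental are
#' annotated via `harmonic_of`.
#'
#' @param spectrum A [power_spectrum()].
#' @param local_window_hz Half-width of the baseline window, Hz (default 5).
#' @param k_sd Detection threshold in local SD units (default 2).
#' @param candidate_bases Mains frequencies to scan (default `c(50, 60)`).
#' @param max_harmonics Highest harmonic order scanned (default 4);
#'   harmonics at or above Nyquist are skipped.
#' @param exclusion_hz Half-width of the exclusion zone, Hz (default 1).
#' @param require_fundamental Only report a harmonic (order 2 and up) when
#'   its base frequency was itself detected (default `TRUE`): a mains
#'   harmonic without its fundamental is physically implausible, and the
#'   gate removes most isolated chance exceedances at harmonic candidates.
#' @param pool_leads Mains interference is common-mode across electrodes,
#'   so by default the rule is evaluated once per record on the
#'   lead-averaged log spectrum (peaks report `lead = NA`, meaning pooled),
#'   which averages down estimation noise and keeps the record-level
#'   false-positive rate low. Set `FALSE` to test each lead separately.
#' @return A data frame of class `artifact_peaks` with columns
#'   `center_hz`, `lead` (index, `NA` = pooled), `lead_name`, `excess_sd`,
#'   `harmonic_of` (`NA` for fundamentals). Zero rows when nothing is
#'   detected.
#' @export
detect_artifact_peaks <- function(spectrum, local_window_hz = 5, k_sd = 2,
                                  candidate_bases = c(50, 60),
                                  max_harmonics = 4, exclusion_hz = 1,
                                  pool_leads = TRUE,
                                  require_fundamental = TRUE) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  f <- spectrum$freqs
  df <- f[2] - f[1]
  if (local_window_hz <= df)
    stop_ecg("local_window_hz (%g) must exceed the spectral resolution (%g Hz)",
             local_window_hz, df)
  nyq <- spectrum$fs / 2
  lp <- log10_floor(spectrum$power)
  if (pool_leads) lp <- matrix(colMeans(lp), nrow = 1)
  hits <- list()
  for (base in candidate_bases) {
    if (base >= nyq)
      stop_ecg("candidate base %g Hz is not below Nyquist (%g Hz)", base, nyq)
    for (ld in seq_len(nrow(lp))) {
      fund_detected <- FALSE
      for (h in seq_len(max_harmonics)) {
        fc <- base * h
        if (fc >= nyq) break
        d <- abs(f - fc)
        i_cand <- which(d <= exclusion_hz)
        i_win <- which(d <= local_window_hz & d > exclusion_hz & f <= nyq)
        if (length(i_win) < 5)
          stop_ecg("baseline window around %g Hz has only %d bins (<5); widen local_window_hz or lengthen segment_s",
                   fc, length(i_win))
        mu <- mean(lp[ld, i_win]); s <- sd(lp[ld, i_win])
        stat <- mean(lp[ld, i_cand])
        over <- s > 0 && stat > mu + k_sd * s
        if (h == 1L) fund_detected <- over
        if (over && (h == 1L || fund_detected || !require_fundamental)) {
          hits[[length(hits) + 1L]] <- data.frame(
            center_hz = fc,
            lead = if (pool_leads) NA_integer_ else ld,
            lead_name = if (pool_leads) "pooled" else spectrum$lead_names[ld],
            excess_sd = (stat - mu) / s,
            harmonic_of = if (h > 1) base else NA_real_)
        }
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(center_hz = numeric(0), lead = integer(0),
               lead_name = character(0), excess_sd = numeric(0),
               harmonic_of = numeric(0))
  class(out) <- c("artifact_peaks", "data.frame")
  out
}

#' Band power of a record
#'
#' Integrated one-sided spectral power over a frequency band, per lead.
#' Used by the clinical-band preservation checks (the pipeline is expected
#' to leave 2-30 Hz power essentially untouched).
#'
#' @param record An [ecg_record()].
#' @param band Length-2 Hz band (closed interval).
#' @param ... Passed to [power_spectrum()].
#' @return Numeric vector of band powers (mV^2) per lead.
#' @export
band_power <- function(record, band = c(2, 30), ...) {
  sp <- power_spectrum(record, ...)
  idx <- which(sp$freqs >= band[1] & sp$freqs <= band[2])
  df <- sp$freqs[2] - sp$freqs[1]
  rowSums(sp$power[, idx, drop = FALSE]) * df
}
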