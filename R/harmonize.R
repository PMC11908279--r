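# One causal IIR pass warm-started at steady state for the signal's first
# value (past inputs = x[1], past outputs = x[1] * DC gain), so a constant
# signal passes without any startup transient.
warm_filter <- function(b, a, x) {
  h0 <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1),
                            init = rep(x[1] * h0, length(a) - 1)))
}

# Extend a signal beyond one end by autoregressive forecasting (Burg fit),
# so pads continue both slow drift and in-band oscillations without a kink
# at the boundary. Falls back to odd reflection for degenerate signals.
ar_extend <- function(x, npad, order = 60) {
  n <- length(x)
  fit <- tryCatch(stats::ar(x, aic = FALSE,
                            order.max = min(order, n - 1, floor(n / 4)),
                            method = "burg", demean = TRUE),
                  error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit$ar)))
    return(2 * x[n] - x[seq(n - 1L, n - npad)])
  as.numeric(predict(fit, n.ahead = npad, se.fit = FALSE))
}

#' Zero-phase 1 Hz high-pass filter
#'
#' Order-4 Butterworth high-pass applied forward-backward, so the group
#' delay is zero and ST-segment shape is not skewed. Removes DC and
#' sub-cutoff drift on the selected leads only. To keep edge transients out
#' of the record, each lead is first extended on both sides by
#' autoregressive forecasts (which continue drift and oscillatory content
#' smoothly across the boundary), each pass starts from the steady-state
#' filter state, and the extensions are discarded afterwards.
#'
#' @param record An [ecg_record()].
#' @param cutoff_hz Cutoff frequency, Hz (default 1).
#' @param leads Integer vector of lead indices to filter (default: all).
#' @param order Butterworth order (default 4).
#' @return A filtered `ecg_record`.
#' @export
apply_highpass <- function(record, cutoff_hz = 1, leads = NULL, order = 4) {
  stopifnot(inherits(record, "ecg_record"))
  nyq <- record$fs / 2
  if (cutoff_hz >= nyq)
    stop_ecg("cutoff %g Hz is at or above Nyquist (%g Hz)", cutoff_hz, nyq)
  leads <- leads %||% seq_len(n_leads(record))
  bf <- signal::butter(order, cutoff_hz / nyq, type = "high")
  n <- n_samples(record)
  npad <- min(n - 1L, as.integer(ceiling(3 * record$fs / cutoff_hz)))
  out <- record
  for (ld in leads) {
    x <- record$waveform[ld, ]
    if (all(x == 0)) { out$waveform[ld, ] <- x; next }
    right <- ar_extend(x, npad)
    left <- rev(ar_extend(rev(x), npad))
    xp <- c(left, x, right)
    y <- warm_filter(bf$b, bf$a, xp)
    y <- rev(warm_filter(bf$b, bf$a, rev(y)))
    out$waveform[ld, ] <- y[(npad + 1L):(npad + n)]
  }
  out
}

#' Flatten detected artifact peaks against a LOESS spectral baseline
#'
#' Spectral surgery on the full-length FFT of each affected lead: for each
#' peak, a local-linear LOESS curve is fitted to log10 power over a
#' `+/- neighborhood_hz` band around the peak, with the peak's own
#' `+/- exclusion_hz` bins excluded from the fit. The magnitudes of the
#' excluded bins are then replaced by the LOESS prediction while the
#' original phase is retained, and the time signal is reconstructed by
#' inverse FFT. Bins outside the peak zones are numerically unchanged, so
#' the operation is exactly local in frequency.
#'
#' @param record An [ecg_record()].
#' @param peaks An `artifact_peaks` data frame (from
#'   [detect_artifact_peaks()]); the `lead` column selects which lead each
#'   peak is removed from, with `NA` (a pooled detection) meaning every
#'   lead. An empty peak list returns the input unchanged.
#' @param loess_span LOESS span over the fit window (default 0.75).
#' @param neighborhood_hz Fit-window half-width, Hz (default 5).
#' @param exclusion_hz Replaced-zone half-width, Hz (default 1).
#' @return An `ecg_record` with the peaks flattened.
#' @export
flatten_peaks <- function(record, peaks, loess_span = 0.75,
                          neighborhood_hz = 5, exclusion_hz = 1) {
  stopifnot(inherits(record, "ecg_record"))
  if (is.null(peaks) || nrow(peaks) == 0L) return(record)
  n <- n_samples(record)
  fs <- record$fs
  nyq <- fs / 2
  f_full <- (seq_len(n) - 1) * fs / n        # full FFT bin frequencies
  half <- which(f_full <= nyq)               # positive-frequency half
  out <- record
  affected <- if (anyNA(peaks$lead)) seq_len(n_leads(record)) else
    sort(unique(peaks$lead))                 # NA lead = pooled = all leads
  for (ld in affected) {
    X <- fft(record$waveform[ld, ])
    lp <- log10_floor(Mod(X[half])^2)
    for (r in which(is.na(peaks$lead) | peaks$lead == ld)) {
      fc <- peaks$center_hz[r]
      if (fc - exclusion_hz <= 0)
        stop_ecg("peak at %g Hz reaches DC; cannot flatten", fc)
      if (fc + exclusion_hz >= nyq)
        stop_ecg("peak at %g Hz reaches Nyquist; cannot flatten", fc)
      d <- abs(f_full[half] - fc)
      i_peak <- which(d <= exclusion_hz)
      i_fit <- which(d <= neighborhood_hz & d > exclusion_hz)
      fit <- stats::loess(y ~ x,
                          data = data.frame(x = f_full[half][i_fit],
                                            y = lp[i_fit]),
                          span = loess_span, degree = 1,
                          family = "gaussian",
                          control = stats::loess.control(surface = "direct"))
      lp_hat <- stats::predict(fit, newdata = data.frame(x = f_full[half][i_peak]))
      new_mag <- sqrt(10^lp_hat)
      idx <- half[i_peak]
      X[idx] <- new_mag * exp(1i * Arg(X[idx]))
      mirror <- n - idx + 2L                 # conjugate-symmetric partners
      keep <- mirror >= 1L & mirror <= n & mirror != idx
      X[mirror[keep]] <- Conj(X[idx[keep]])
      lp[i_peak] <- lp_hat
    }
    out$waveform[ld, ] <- Re(fft(X, inverse = TRUE)) / n
  }
  out
}

#' Build a reference amplitude profile from a record collection
#'
#' Pools all samples per lead across the supplied records and takes the
#' (p1, p99) amplitude percentiles. The resulting profile is the target that
#' [amplitude_match()] rescales other datasets to, playing the role of the
#' reference dataset in a cross-dataset harmonization.
#'
#' @param records A list of [ecg_record()] objects with identical lead
#'   counts.
#' @param probs Lower/upper percentile pair (default `c(0.01, 0.99)`).
#' @param provenance Free-text description stored in the profile.
#' @param edge_guard_s Seconds excluded at each record end when pooling
#'   samples (default 0.5, capped at a quarter of each record), matching
#'   the convention of [amplitude_match()] so that matching a record to a
#'   profile built from itself is an exact fixed point.
#' @return An object of class `reference_profile` with per-lead `p_low`,
#'   `p_high`.
#' @export
build_reference_profile <- function(records, probs = c(0.01, 0.99),
                                    provenance = "user-built",
                                    edge_guard_s = 0.5) {
  if (inherits(records, "ecg_record")) records <- list(records)
  if (!length(records)) stop_ecg("need at least one record")
  nl <- vapply(records, n_leads, integer(1))
  if (length(unique(nl)) != 1L)
    stop_ecg("records have inconsistent lead counts: %s",
             paste(unique(nl), collapse = ", "))
  L <- nl[1]
  interior_of <- function(r) {
    n <- n_samples(r)
    guard <- min(as.integer(round(edge_guard_s * r$fs)), n %/% 4)
    (guard + 1L):(n - guard)
  }
  p_low <- p_high <- numeric(L)
  for (ld in seq_len(L)) {
    pooled <- unlist(lapply(records, function(r)
      r$waveform[ld, interior_of(r)]))
    q <- quantile(pooled, probs, names = FALSE)
    p_low[ld] <- q[1]; p_high[ld] <- q[2]
  }
  if (any(!(p_high > p_low)))
    stop_ecg("degenerate profile: p%g == p%g on lead(s) %s (constant signal?)",
             100 * probs[1], 100 * probs[2],
             paste(which(!(p_high > p_low)), collapse = ", "))
  structure(list(p_low = p_low, p_high = p_high, probs = probs,
                 lead_names = records[[1]]$lead_names,
                 provenance = provenance),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("<reference_profile> %d lead(s), p%g-p%g spans %s mV (%s)\n",
              length(x$p_low), 100 * x$probs[1], 100 * x$probs[2],
              paste(signif(x$p_high - x$p_low, 3), collapse = "/"),
              x$provenance))
  invisible(x)
}

#' Scale a record's per-lead amplitude range to a reference profile
#'
#' Multiplies each lead by `reference span / record span`, where span is
#' the (p1, p99) percentile range, so the rescaled record occupies the
#' reference dataset's amplitude range. Purely multiplicative: waveform
#' shape (per-lead correlation with the input) is exactly preserved, the
#' operation is idempotent, and `match(c*x, ref) == match(x, ref)` for any
#' `c > 0`. A zero-span (flat) lead is left unscaled and flagged with a
#' warning rather than failing the record.
#'
#' @param record An [ecg_record()].
#' @param reference A [build_reference_profile()] result with a matching
#'   lead count.
#' @param edge_guard_s Seconds excluded at each end of the record when
#'   estimating the percentile span (default 0.5, capped at a quarter of
#'   the record). Earlier pipeline stages are exact in the record interior
#'   but can leave small residuals at the very edges; keeping those out of
#'   the span estimate keeps the scale factors unbiased. The scaling
#'   itself is applied to the whole record.
#' @return An `ecg_record` with attribute `"scale_factors"` holding the
#'   per-lead multipliers applied.
#' @export
amplitude_match <- function(record, reference, edge_guard_s = 0.5) {
  stopifnot(inherits(record, "ecg_record"),
            inherits(reference, "reference_profile"))
  L <- n_leads(record)
  if (L != length(reference$p_low))
    stop_ecg("record has %d leads but profile has %d", L,
             length(reference$p_low))
  n <- n_samples(record)
  guard <- min(as.integer(round(edge_guard_s * record$fs)), n %/% 4)
  interior <- (guard + 1L):(n - guard)
  scale <- rep(1, L)
  skipped <- integer(0)
  for (ld in seq_len(L)) {
    q <- quantile(record$waveform[ld, interior], reference$probs,
                  names = FALSE)
    span <- q[2] - q[1]
    if (span <= 0) { skipped <- c(skipped, ld); next }
    scale[ld] <- (reference$p_high[ld] - reference$p_low[ld]) / span
  }
  if (length(skipped))
    warning(sprintf("zero-span lead(s) %s left unscaled",
                    paste(skipped, collapse = ", ")), call. = FALSE)
  out <- record
  out$waveform <- record$waveform * scale
  attr(out, "scale_factors") <- scale
  attr(out, "skipped_leads") <- skipped
  out
}

#' Harmonization configuration
#'
#' @param highpass_cutoff_hz High-pass cutoff (default 1 Hz).
#' @param excess_threshold Log10 excess above which the high-pass fires
#'   (default 1, one logarithmic unit).
#' @param trigger_mode `"per_lead"` (filter exactly the leads whose excess
#'   exceeds the threshold) or `"any_lead"` (any triggering lead filters the
#'   whole record).
#' @param k_sd Peak-detection threshold in SD units (default 2).
#' @param candidate_bases Mains candidates, Hz (default `c(50, 60)`).
#' @param max_harmonics Highest harmonic scanned (default 4).
#' @param local_window_hz,exclusion_hz Detector/flattener window geometry.
#' @param loess_span LOESS span for flattening (default 0.75).
#' @param segment_s,overlap_frac Welch parameters for the peak-detection
#'   spectrum (default 2 s segments: enough averaging for a stable local
#'   SD).
#' @param segment_s_lowfreq Welch segment length for the low-frequency
#'   trigger (default 5 s). The sub-1 Hz band needs finer frequency
#'   resolution than peak detection: at 0.2 Hz resolution the band holds
#'   four bins and the heartbeat fundamental's leakage no longer dominates
#'   it.
#' @param pool_leads Evaluate the peak rule on the lead-averaged spectrum
#'   (default `TRUE`; see [detect_artifact_peaks()]).
#' @param require_fundamental Gate harmonic detections on the fundamental
#'   (default `TRUE`; see [detect_artifact_peaks()]).
#' @param stages Named logical vector enabling `highpass`, `flatten`,
#'   `scale`.
#' @return A list of class `harmonize_config`.
#' @export
harmonize_config <- function(highpass_cutoff_hz = 1, excess_threshold = 1,
                             trigger_mode = c("per_lead", "any_lead"),
                             k_sd = 2, candidate_bases = c(50, 60),
                             max_harmonics = 4, local_window_hz = 5,
                             exclusion_hz = 1, loess_span = 0.75,
                             segment_s = 2, overlap_frac = 0.5,
                             segment_s_lowfreq = 5, pool_leads = TRUE,
                             require_fundamental = TRUE,
                             stages = c(highpass = TRUE, flatten = TRUE,
                                        scale = TRUE)) {
  trigger_mode <- match.arg(trigger_mode)
  structure(list(highpass_cutoff_hz = highpass_cutoff_hz,
                 excess_threshold = excess_threshold,
                 trigger_mode = trigger_mode, k_sd = k_sd,
                 candidate_bases = candidate_bases,
                 max_harmonics = max_harmonics,
                 local_window_hz = local_window_hz,
                 exclusion_hz = exclusion_hz, loess_span = loess_span,
                 segment_s = segment_s, overlap_frac = overlap_frac,
                 segment_s_lowfreq = segment_s_lowfreq,
                 pool_leads = pool_leads,
                 require_fundamental = require_fundamental, stages = stages),
            class = "harmonize_config")
}

#' Run the full three-stage harmonization pipeline on one record
#'
#' Stages run in fixed order, each only when its trigger fires:
#' \enumerate{
#'   \item Conditional high-pass: leads whose sub-1 Hz log-power excess
#'     exceeds one logarithmic unit are high-pass filtered at 1 Hz.
#'   \item Artifact-peak removal: 50/60 Hz candidates (and harmonics)
#'     exceeding the local mean by 2 SD are flattened against a LOESS
#'     spectral baseline.
#'   \item Amplitude matching: each lead is rescaled to the reference
#'     profile's percentile span.
#' }
#' Every decision is recorded in a `harmonization_log`, which together with
#' the input reproduces the output bit-exactly via [replay_harmonization()].
#'
#' @param record An [ecg_record()].
#' @param reference A [build_reference_profile()] result, or `NULL` to skip
#'   the scaling stage.
#' @param config A [harmonize_config()].
#' @return A list with elements `record` (harmonized) and `log`
#'   (`harmonization_log`).
#' @export
harmonize_record <- function(record, reference = NULL,
                             config = harmonize_config()) {
  stopifnot(inherits(record, "ecg_record"),
            inherits(config, "harmonize_config"))
  st <- config$stages
  sp <- power_spectrum(record, config$segment_s_lowfreq, config$overlap_frac)
  excess <- lowfreq_excess(sp)
  hp_leads <- integer(0)
  if (isTRUE(st[["highpass"]])) {
    trig <- which(excess > config$excess_threshold)
    hp_leads <- if (config$trigger_mode == "any_lead" && length(trig))
      seq_len(n_leads(record)) else trig
    if (length(hp_leads))
      record <- apply_highpass(record, config$highpass_cutoff_hz, hp_leads)
  }
  peaks <- empty_peaks()
  if (isTRUE(st[["flatten"]])) {
    sp2 <- power_spectrum(record, config$segment_s, config$overlap_frac)
    peaks <- detect_artifact_peaks(sp2, config$local_window_hz, config$k_sd,
                                   config$candidate_bases,
                                   config$max_harmonics, config$exclusion_hz,
                                   pool_leads = config$pool_leads,
                                   require_fundamental = config$require_fundamental)
    if (nrow(peaks))
      record <- flatten_peaks(record, peaks, config$loess_span,
                              config$local_window_hz, config$exclusion_hz)
  }
  scale <- rep(1, n_leads(record))
  skipped <- integer(0)
  if (isTRUE(st[["scale"]]) && !is.null(reference)) {
    record <- amplitude_match(record, reference)
    scale <- attr(record, "scale_factors")
    skipped <- attr(record, "skipped_leads")
  }
  log <- structure(list(lowfreq_excess = excess,
                        highpass_applied = seq_len(n_leads(record)) %in% hp_leads,
                        peaks_removed = peaks,
                        scale_factors = scale,
                        skipped_leads = skipped,
                        config = config),
                   class = "harmonization_log")
  list(record = record, log = log)
}

empty_peaks <- function() {
  out <- data.frame(center_hz = numeric(0), lead = integer(0),
                    lead_name = character(0), excess_sd = numeric(0),
                    harmonic_of = numeric(0))
  class(out) <- c("artifact_peaks", "data.frame")
  out
}

#' @export
print.harmonization_log <- function(x, ...) {
  cat(sprintf("<harmonization_log> high-pass on %d lead(s); %d peak(s) flattened; scale %s\n",
              sum(x$highpass_applied), nrow(x$peaks_removed),
              paste(signif(range(x$scale_factors), 3), collapse = "-")))
  invisible(x)
}

#' Replay a harmonization from its decision log
#'
#' Re-applies exactly the decisions recorded in a [harmonize_record()] log —
#' which leads were filtered, which peaks were flattened, which scale
#' factors were applied — without re-running any trigger. Given the same
#' input record, the result is bit-identical to the original output, which
#' makes every harmonized dataset reproducible from (input, log) alone.
#'
#' @param record The original (pre-harmonization) [ecg_record()].
#' @param log A `harmonization_log`.
#' @return The harmonized `ecg_record`.
#' @export
replay_harmonization <- function(record, log) {
  stopifnot(inherits(log, "harmonization_log"))
  cfg <- log$config
  hp <- which(log$highpass_applied)
  if (length(hp))
    record <- apply_highpass(record, cfg$highpass_cutoff_hz, hp)
  if (nrow(log$peaks_removed))
    record <- flatten_peaks(record, log$peaks_removed, cfg$loess_span,
                            cfg$local_window_hz, cfg$exclusion_hz)
  record$waveform <- record$waveform * log$scale_factors
  record
}
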