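#' Tile a record into equal-width segments per lead
#'
#' Contiguous half-open sample intervals `[start, end)` in 0-based
#' indexing: each lead is split into `n_segments_per_lead` spans of width
#' `floor(n_samples / n_segments)`, with the last segment absorbing the
#' remainder. The spans tile the signal exactly, without overlap.
#'
#' @param record An [ecg_record()].
#' @param n_segments_per_lead Positive segment count, at most the sample
#'   count.
#' @return Data frame with columns `lead` (1-based index), `segment`,
#'   `start`, `end` (0-based, half-open).
#' @export
segment_signal <- function(record, n_segments_per_lead = 10) {
  stopifnot(inherits(record, "ecg_record"))
  n <- n_samples(record)
  k <- n_segments_per_lead
  if (k <= 0) stop_ecg("`n_segments_per_lead` must be positive")
  if (k > n) stop_ecg("more segments (%d) than samples (%d)", k, n)
  width <- n %/% k
  starts <- (seq_len(k) - 1L) * width
  ends <- c(starts[-1L], n)
  do.call(rbind, lapply(seq_len(n_leads(record)), function(ld)
    data.frame(lead = ld, segment = seq_len(k), start = starts, end = ends)))
}

apply_mask <- function(waveform, segs, mask, baseline_values) {
  off <- which(mask == 0)
  for (r in off) {
    ld <- segs$lead[r]
    cols <- (segs$start[r] + 1L):segs$end[r]
    waveform[ld, cols] <- baseline_values[ld]
  }
  waveform
}

#' LIME-style segment attribution for a multichannel 1-D signal
#'
#' Explains one label's score from any black-box `score_fn` by localized
#' perturbation: the record is tiled into segments ([segment_signal()]),
#' random binary masks switch segments off (replaced by a baseline value),
#' each perturbed record is scored, and a ridge-penalized weighted linear
#' surrogate is fitted in mask space. Perturbations are weighted by an
#' exponential kernel on the mask's Hamming distance from the unperturbed
#' mask, `exp(-n_off / kernel_width^2)`. The per-segment coefficients are
#' the attribution: positive weights mark regions that support the
#' prediction. Each label is analysed independently — only the requested
#' label's output is ever read.
#'
#' @param score_fn Function mapping an [ecg_record()] to a (possibly named)
#'   numeric vector of per-label scores.
#' @param record The record to explain.
#' @param label Label name or index into `score_fn`'s output.
#' @param n_segments Segments per lead (default 10; 1 s windows on a 10 s
#'   record, about one beat at 60 bpm).
#' @param n_perturbations Number of random masks (default 1000). The
#'   unperturbed mask is always included as the first perturbation.
#' @param kernel_width Kernel width; default `0.25 * sqrt(n segments)`,
#'   the conventional LIME choice.
#' @param baseline `"zero"` (masked segments set to 0) or `"mean"` (lead
#'   mean).
#' @param ridge Ridge penalty on the surrogate coefficients (default 1e-6;
#'   numerical stabilizer, intercept unpenalized).
#' @param seed Integer seed; attributions are deterministic under it.
#' @return An object of class `lime_attribution`: `segments` (with a
#'   `weight` column), `intercept`, `r_squared` (weighted, `NA` when the
#'   score is constant), plus provenance fields.
#' @export
lime_attribute <- function(score_fn, record, label, n_segments = 10,
                           n_perturbations = 1000, kernel_width = NULL,
                           baseline = c("zero", "mean"), ridge = 1e-6,
                           seed = NULL) {
  stopifnot(is.function(score_fn), inherits(record, "ecg_record"))
  baseline <- match.arg(baseline)
  segs <- segment_signal(record, n_segments)
  d <- nrow(segs)
  kernel_width <- kernel_width %||% (0.25 * sqrt(d))
  baseline_values <- if (baseline == "zero") rep(0, n_leads(record))
  else rowMeans(record$waveform)
  with_seed(seed, {
    masks <- matrix(rbinom(n_perturbations * d, 1, 0.5),
                    nrow = n_perturbations)
    masks[1L, ] <- 1L
    y <- numeric(n_perturbations)
    proto <- record
    for (i in seq_len(n_perturbations)) {
      proto$waveform <- apply_mask(record$waveform, segs, masks[i, ],
                                   baseline_values)
      out <- tryCatch(score_fn(proto), error = function(e)
        stop_ecg("score_fn failed on mask %s: %s",
                 paste(masks[i, ], collapse = ""), conditionMessage(e)))
      y[i] <- out[[label]]
    }
    n_off <- rowSums(1 - masks)
    w <- exp(-n_off / kernel_width^2)
    Xc <- cbind(1, masks)
    A <- crossprod(Xc, w * Xc) + ridge * diag(c(0, rep(1, d)))
    beta <- solve(A, crossprod(Xc, w * y))
    fitted <- as.vector(Xc %*% beta)
    wm <- sum(w * y) / sum(w)
    sst <- sum(w * (y - wm)^2)
    constant_fn <- sst <= .Machine$double.eps * max(1, sum(w * y^2))
    r2 <- if (constant_fn) NA_real_ else 1 - sum(w * (y - fitted)^2) / sst
    segs$weight <- if (constant_fn) rep(0, d) else as.vector(beta[-1L])
    structure(list(label = label, segments = segs,
                   intercept = as.vector(beta[1L]), r_squared = r2,
                   n_perturbations = n_perturbations,
                   kernel_width = kernel_width, baseline = baseline,
                   seed = seed),
              class = "lime_attribution")
  })
}

#' @export
print.lime_attribution <- function(x, ...) {
  top <- x$segments[order(-x$segments$weight), ][1L, ]
  cat(sprintf("<lime_attribution> label=%s, %d segments, R2=%s\n",
              as.character(x$label), nrow(x$segments),
              if (is.na(x$r_squared)) "NA (constant score)"
              else sprintf("%.3f", x$r_squared)))
  cat(sprintf("  strongest positive segment: lead %d, samples [%d, %d), weight %.4g\n",
              top$lead, top$start, top$end, top$weight))
  invisible(x)
}
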