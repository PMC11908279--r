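#' Multichannel ECG record
#'
#' The basic waveform container every pipeline stage consumes: a numeric
#' matrix of `n_leads x n_samples` in millivolts plus the sampling rate.
#' Optional demographics (age in years, sex) travel with the record so
#' downstream audits can group by them. Synthetic records additionally carry
#' a `contamination` matrix (the exact sum of everything injected on top of
#' the clean trace) which serves as an oracle in tests: subtracting it
#' recovers the clean waveform.
#'
#' @param waveform Numeric matrix, `n_leads x n_samples`, millivolts.
#' @param fs Sampling rate in Hz.
#' @param lead_names Character vector of length `n_leads`; defaults to
#'   the standard 12-lead names when `n_leads == 12`, else `"L1"..`.
#' @param age,sex Optional demographics.
#' @param source_id Free-text provenance string.
#' @param contamination Optional matrix (same shape) of additive
#'   contamination already contained in `waveform`.
#' @param meta List of additional metadata (injection log, lead scales, ...).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(waveform, fs, lead_names = NULL, age = NULL,
                       sex = NULL, source_id = "unknown",
                       contamination = NULL, meta = list()) {
  if (!is.matrix(waveform) || !is.numeric(waveform))
    stop_ecg("`waveform` must be a numeric matrix (n_leads x n_samples)")
  if (anyNA(waveform) || any(!is.finite(waveform))) {
    bad <- which(!is.finite(waveform))[1L]
    stop_ecg("waveform contains a non-finite value at flat index %d", bad)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_ecg("`fs` must be a positive sampling rate in Hz")
  n_leads <- nrow(waveform)
  if (n_leads < 1L) stop_ecg("record needs at least one lead")
  if (is.null(lead_names)) {
    lead_names <- if (n_leads == 12L)
      c("I", "II", "III", "aVR", "aVL", "aVF",
        "V1", "V2", "V3", "V4", "V5", "V6")
    else paste0("L", seq_len(n_leads))
  }
  if (length(lead_names) != n_leads)
    stop_ecg("`lead_names` length (%d) != number of leads (%d)",
             length(lead_names), n_leads)
  if (!is.null(contamination)) {
    stopifnot(is.matrix(contamination),
              all(dim(contamination) == dim(waveform)))
  }
  structure(list(waveform = waveform, fs = fs, lead_names = lead_names,
                 age = age, sex = sex, source_id = source_id,
                 contamination = contamination, meta = meta),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d lead(s) x %d samples @ %g Hz (%.1f s), source=%s\n",
              nrow(x$waveform), ncol(x$waveform), x$fs,
              ncol(x$waveform) / x$fs, x$source_id))
  if (!is.null(x$contamination))
    cat("  carries a stored contamination trace (synthetic oracle)\n")
  invisible(x)
}

#' @export
dim.ecg_record <- function(x) dim(x$waveform)

n_samples <- function(record) ncol(record$waveform)
n_leads <- function(record) nrow(record$waveform)

#' Duration of a record in seconds
#' @param record An `ecg_record`.
#' @return Seconds.
#' @export
record_duration <- function(record) n_samples(record) / record$fs

#' Multilabel prediction set
#'
#' Container for model outputs on a dataset: an `n x L` score matrix in
#' `[0, 1]`, the matching binary ground-truth label matrix, and optional
#' per-record demographics used by the fairness audit.
#'
#' @param scores Numeric `n x L` matrix of scores in `[0, 1]`.
#' @param labels Binary `n x L` matrix (0/1).
#' @param record_ids Optional identifiers (default `"r1"..`).
#' @param label_names Optional column names (default `"label1"..`).
#' @param age Optional numeric vector of ages (years), length `n`.
#' @param sex Optional character/factor vector, length `n`.
#' @param group Optional explicit grouping vector, length `n` (synthetic
#'   generators record their design groups here).
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(scores, labels, record_ids = NULL,
                           label_names = NULL, age = NULL, sex = NULL,
                           group = NULL) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  if (!all(dim(scores) == dim(labels)))
    stop_ecg("scores (%dx%d) and labels (%dx%d) shapes differ",
             nrow(scores), ncol(scores), nrow(labels), ncol(labels))
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    bad <- which(is.na(scores) | scores < 0 | scores > 1, arr.ind = TRUE)[1L, ]
    stop_ecg("score outside [0,1] at row %d, column %d", bad[1L], bad[2L])
  }
  if (!all(labels %in% c(0, 1)))
    stop_ecg("labels must be binary 0/1")
  n <- nrow(scores); L <- ncol(scores)
  record_ids <- record_ids %||% paste0("r", seq_len(n))
  label_names <- label_names %||% (colnames(scores) %||% paste0("label", seq_len(L)))
  stopifnot(length(record_ids) == n, length(label_names) == L)
  if (!is.null(age) && length(age) != n) stop_ecg("`age` must have length n")
  if (!is.null(sex) && length(sex) != n) stop_ecg("`sex` must have length n")
  if (!is.null(group) && length(group) != n) stop_ecg("`group` must have length n")
  colnames(scores) <- colnames(labels) <- label_names
  structure(list(record_ids = as.character(record_ids), scores = scores,
                 labels = labels, label_names = label_names,
                 age = age, sex = sex, group = group),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d records x %d labels", nrow(x$scores),
              ncol(x$scores)))
  extras <- c(if (!is.null(x$age)) "age", if (!is.null(x$sex)) "sex",
              if (!is.null(x$group)) "group")
  if (length(extras)) cat(" (with ", paste(extras, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Subset a prediction set by record index
#' @param predset A `prediction_set`.
#' @param idx Integer vector of record indices.
#' @return A `prediction_set` restricted to `idx`.
#' @export
subset_records <- function(predset, idx) {
  prediction_set(predset$scores[idx, , drop = FALSE],
                 predset$labels[idx, , drop = FALSE],
                 record_ids = predset$record_ids[idx],
                 label_names = predset$label_names,
                 age = predset$age[idx], sex = predset$sex[idx],
                 group = predset$group[idx])
}
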