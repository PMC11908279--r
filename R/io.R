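sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an ECG record to disk
#'
#' Two on-disk forms are supported. `"csv"` writes the waveform as a plain
#' leads-by-samples numeric matrix plus a JSON sidecar
#' (`<stem>.json`) carrying the sampling rate, lead names and units —
#' delimited waveforms without that sidecar are refused on read, because a
#' matrix of numbers with no units or rate is not a signal. `"wfdb"`
#' writes a minimal WFDB pair (`<stem>.hea` text header and `<stem>.dat`
#' 16-bit little-endian samples, interleaved across signals) with the
#' standard gain/baseline digital-to-physical convention
#' `physical = (digital - baseline) / gain`, in mV.
#'
#' @param record An [ecg_record()].
#' @param path Output path; for `"wfdb"` the extension is ignored and
#'   `.hea`/`.dat` are written next to it.
#' @param format `"csv"` or `"wfdb"`.
#' @param gain WFDB gain in ADC units per mV (default 1000, i.e. 1 uV
#'   resolution).
#' @return The main file path, invisibly.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb"),
                         gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  format <- match.arg(format)
  stem <- tools::file_path_sans_ext(path)
  if (format == "csv") {
    if (tolower(tools::file_ext(path)) != "csv") path <- paste0(stem, ".csv")
    utils::write.table(record$waveform, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(list(fs = record$fs, lead_names = record$lead_names,
                              units = "mV", n_leads = n_leads(record),
                              n_samples = n_samples(record),
                              source_id = record$source_id),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  # WFDB format 16, single interleaved .dat
  nl <- n_leads(record); ns <- n_samples(record)
  baseline <- 0L
  digital <- round(record$waveform * gain) + baseline
  if (any(abs(digital) > 32767))
    stop_ecg("waveform exceeds int16 range at gain %g; lower the gain", gain)
  digital <- matrix(as.integer(digital), nl, ns)
  checksums <- as.integer(rowSums(digital) %% 65536)
  checksums <- ifelse(checksums > 32767, checksums - 65536L, checksums)
  rec_name <- basename(stem)
  hea <- c(sprintf("%s %d %g %d", rec_name, nl, record$fs, ns),
           sprintf("%s.dat 16 %g(%d)/mV 16 0 %d %d 0 %s",
                   rec_name, gain, baseline, digital[, 1], checksums,
                   record$lead_names))
  writeLines(hea, paste0(stem, ".hea"))
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(as.vector(digital)), con, size = 2, endian = "little")
  invisible(paste0(stem, ".hea"))
}

parse_wfdb_header <- function(hea_path) {
  lines <- trimws(readLines(hea_path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  top <- strsplit(lines[1], "\\s+")[[1]]
  if (length(top) < 4) stop_ecg("malformed WFDB header: %s", hea_path)
  n_sig <- as.integer(top[2]); fs <- as.numeric(top[3])
  n_samp <- as.integer(top[4])
  sig <- lines[1 + seq_len(n_sig)]
  if (anyNA(sig)) stop_ecg("WFDB header lists %d signals but has fewer lines",
                           n_sig)
  parse_sig <- function(ln) {
    f <- strsplit(ln, "\\s+")[[1]]
    fmt <- f[2]
    if (fmt != "16") stop_ecg("only WFDB format 16 is supported, got %s", fmt)
    gspec <- f[3]
    units <- sub("^[^/]*/?", "", gspec)
    gb <- sub("/.*$", "", gspec)
    baseline <- if (grepl("\\(", gb))
      as.numeric(sub(".*\\(([-0-9.]+)\\).*", "\\1", gb)) else 0
    gain <- as.numeric(sub("\\(.*$", "", gb))
    if (is.na(gain) || gain == 0) gain <- 200  # WFDB default gain
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else NA
    list(file = f[1], gain = gain, baseline = baseline,
         units = if (nzchar(units)) units else "mV", desc = desc)
  }
  sigs <- lapply(sig, parse_sig)
  list(n_sig = n_sig, fs = fs, n_samp = n_samp, sigs = sigs)
}

#' Read an ECG record from disk
#'
#' Dispatches on extension: `.hea` reads a WFDB pair (format 16 only),
#' honoring each signal's gain and baseline so the returned waveform is in
#' physical units (mV); `.csv` reads a delimited leads-by-samples matrix
#' and requires the JSON sidecar written by [write_record()] — a delimited
#' matrix without units and sampling rate is refused.
#'
#' @param path Path to a `.hea` or `.csv` file.
#' @return An [ecg_record()].
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop_ecg("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "hea") {
    hdr <- parse_wfdb_header(path)
    dat <- file.path(dirname(path), hdr$sigs[[1]]$file)
    if (!file.exists(dat)) stop_ecg("missing WFDB data file: %s", dat)
    raw <- readBin(dat, integer(), n = hdr$n_sig * hdr$n_samp + 1L,
                   size = 2, endian = "little")
    if (length(raw) != hdr$n_sig * hdr$n_samp)
      stop_ecg("truncated WFDB data: expected %d samples, found %d",
               hdr$n_sig * hdr$n_samp, length(raw))
    digital <- matrix(raw, nrow = hdr$n_sig)
    phys <- digital
    for (i in seq_len(hdr$n_sig))
      phys[i, ] <- (digital[i, ] - hdr$sigs[[i]]$baseline) / hdr$sigs[[i]]$gain
    leads <- vapply(hdr$sigs, function(s)
      if (is.na(s$desc)) NA_character_ else s$desc, character(1))
    if (anyNA(leads)) leads <- NULL
    return(ecg_record(phys, fs = hdr$fs, lead_names = leads,
                      source_id = basename(tools::file_path_sans_ext(path))))
  }
  if (ext %in% c("csv", "tsv", "txt")) {
    sc <- sidecar_path(path)
    if (!file.exists(sc))
      stop_ecg(paste0("delimited waveform %s has no sidecar %s; a matrix ",
                      "without sampling rate and units is not a signal"),
               path, sc)
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    wv <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(wv) <- NULL
    if (anyNA(wv)) {
      bad <- which(is.na(wv), arr.ind = TRUE)[1L, ]
      stop_ecg("NaN in waveform at lead %d, sample %d", bad[1], bad[2])
    }
    if (!is.null(meta$n_samples) && ncol(wv) != meta$n_samples)
      stop_ecg("truncated waveform: sidecar promises %d samples, file has %d",
               meta$n_samples, ncol(wv))
    return(ecg_record(wv, fs = meta$fs, lead_names = meta$lead_names,
                      source_id = meta$source_id %||% basename(path)))
  }
  stop_ecg("unrecognized record format: .%s (use .hea or .csv)", ext)
}

#' Read a prediction set from score/label/metadata CSVs
#'
#' All files share a `record_id` first column; scores and labels share
#' their remaining (label) columns. Any identifier present in one file but
#' not another is enumerated in the error. Scores are validated into
#' `[0, 1]` and labels to binary.
#'
#' @param scores_path,labels_path CSVs of per-record per-label values.
#' @param meta_path Optional CSV with `record_id` and any of `age`, `sex`,
#'   `group`.
#' @return A [prediction_set()].
#' @export
read_prediction_set <- function(scores_path, labels_path, meta_path = NULL) {
  sc <- utils::read.csv(scores_path, check.names = FALSE)
  lb <- utils::read.csv(labels_path, check.names = FALSE)
  for (d in list(sc, lb)) if (names(d)[1] != "record_id")
    stop_ecg("first column must be `record_id`")
  mismatch <- c(setdiff(sc$record_id, lb$record_id),
                setdiff(lb$record_id, sc$record_id))
  if (length(mismatch))
    stop_ecg("record ids not shared by scores and labels: %s",
             paste(unique(mismatch), collapse = ", "))
  lb <- lb[match(sc$record_id, lb$record_id), ]
  if (!identical(sort(names(sc)), sort(names(lb))))
    stop_ecg("score and label files carry different label columns")
  lb <- lb[, names(sc)]
  age <- sex <- group <- NULL
  if (!is.null(meta_path)) {
    mt <- utils::read.csv(meta_path, check.names = FALSE)
    missing_ids <- setdiff(sc$record_id, mt$record_id)
    if (length(missing_ids))
      stop_ecg("metadata is missing record id(s): %s",
               paste(missing_ids, collapse = ", "))
    mt <- mt[match(sc$record_id, mt$record_id), ]
    age <- mt$age; sex <- mt$sex; group <- mt$group
  }
  prediction_set(unname(as.matrix(sc[, -1, drop = FALSE])),
                 unname(as.matrix(lb[, -1, drop = FALSE])),
                 record_ids = sc$record_id,
                 label_names = names(sc)[-1],
                 age = age, sex = sex, group = group)
}

#' Write a prediction set as score/label/metadata CSVs
#'
#' @param predset A [prediction_set()].
#' @param stem Output path stem; writes `<stem>_scores.csv`,
#'   `<stem>_labels.csv` and, when demographics exist, `<stem>_meta.csv`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_prediction_set <- function(predset, stem) {
  stopifnot(inherits(predset, "prediction_set"))
  paths <- c(scores = paste0(stem, "_scores.csv"),
             labels = paste0(stem, "_labels.csv"))
  utils::write.csv(data.frame(record_id = predset$record_ids, predset$scores,
                              check.names = FALSE),
                   paths["scores"], row.names = FALSE)
  utils::write.csv(data.frame(record_id = predset$record_ids, predset$labels,
                              check.names = FALSE),
                   paths["labels"], row.names = FALSE)
  if (!is.null(predset$age) || !is.null(predset$sex) || !is.null(predset$group)) {
    mt <- data.frame(record_id = predset$record_ids)
    if (!is.null(predset$age)) mt$age <- predset$age
    if (!is.null(predset$sex)) mt$sex <- predset$sex
    if (!is.null(predset$group)) mt$group <- predset$group
    paths <- c(paths, meta = paste0(stem, "_meta.csv"))
    utils::write.csv(mt, paths["meta"], row.names = FALSE)
  }
  invisible(paths)
}

#' Serialize / read a reference amplitude profile as JSON
#'
#' @param profile A [build_reference_profile()] result.
#' @param path JSON path.
#' @return `write_reference_profile` returns `path` invisibly;
#'   `read_reference_profile` returns a `reference_profile`.
#' @export
write_reference_profile <- function(profile, path) {
  stopifnot(inherits(profile, "reference_profile"))
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_profile
#' @export
read_reference_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(p_low = as.numeric(x$p_low), p_high = as.numeric(x$p_high),
                 probs = as.numeric(x$probs), lead_names = x$lead_names,
                 provenance = x$provenance),
            class = "reference_profile")
}

#' Serialize / read a harmonization decision log as JSON
#'
#' The JSON log plus the original input reproduce the harmonized output
#' bit-exactly through [replay_harmonization()].
#'
#' @param log A `harmonization_log` from [harmonize_record()].
#' @param path JSON path.
#' @return `write_harmonization_log` returns `path` invisibly;
#'   `read_harmonization_log` returns a `harmonization_log`.
#' @export
write_harmonization_log <- function(log, path) {
  stopifnot(inherits(log, "harmonization_log"))
  x <- unclass(log)
  x$config <- unclass(x$config)
  x$peaks_removed <- as.data.frame(x$peaks_removed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_harmonization_log
#' @export
read_harmonization_log <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- x$config
  cfg$stages <- unlist(cfg$stages)
  class(cfg) <- "harmonize_config"
  pk <- as.data.frame(x$peaks_removed)
  if (!nrow(pk)) pk <- empty_peaks() else {
    if (is.null(pk$harmonic_of)) pk$harmonic_of <- NA_real_
    pk$harmonic_of <- suppressWarnings(as.numeric(pk$harmonic_of))
    class(pk) <- c("artifact_peaks", "data.frame")
  }
  structure(list(lowfreq_excess = unlist(x$lowfreq_excess),
                 highpass_applied = as.logical(unlist(x$highpass_applied)),
                 peaks_removed = pk,
                 scale_factors = as.numeric(unlist(x$scale_factors)),
                 skipped_leads = as.integer(unlist(x$skipped_leads)),
                 config = cfg),
            class = "harmonization_log")
}
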