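# EDF (European Data Format) 16-bit codec. Only the features the pipeline
# needs: integer-second recordings, one data-record per second, uniform
# sampling within a channel. Channel labels EEG1/EEG2/EMG map to the
# internal names eeg_frontal/eeg_parietal/emg.

EDF_LABEL_MAP <- c(EEG1 = "eeg_frontal", EEG2 = "eeg_parietal", EMG = "emg")

edf_field <- function(x, width) {
  s <- sprintf("%-*s", width, as.character(x))
  if (nchar(s) > width) s <- substr(s, 1, width)
  s
}

edf_num <- function(x, width = 8) {
  edf_field(formatC(x, format = "g", digits = 6, width = 1), width)
}

#' Write a recording to an EDF file
#'
#' Signals are quantized to 16 bits over a symmetric physical range chosen
#' per channel; the subject/genotype/treatment/injection-time metadata are
#' stored in the EDF patient and recording identification fields so the
#' file round-trips through [read_recording()].
#'
#' @param recording An `eeg_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  chans <- recording$channels
  fs <- recording$fs
  n <- unique(vapply(chans, length, integer(1)))
  if (length(n) != 1) stopf("channels have unequal lengths")
  if (n %% fs != 0) stopf("EDF export requires an integer number of seconds")
  n_rec <- n %/% fs
  labels <- names(EDF_LABEL_MAP)[match(names(chans), EDF_LABEL_MAP)]
  labels[is.na(labels)] <- names(chans)[is.na(labels)]
  ns <- length(chans)

  pmaxs <- vapply(chans, function(x) {
    m <- max(abs(x), 1e-6)
    signif(m * 1.01, 6)
  }, numeric(1))

  meta <- recording$meta
  patient <- edf_field(meta$subject %||% "X", 80)
  rec_id <- edf_field(sprintf("genotype=%s treatment=%s injection_s=%s",
                              meta$genotype %||% NA, meta$treatment %||% NA,
                              meta$injection_time_s %||% NA), 80)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    edf_field("0", 8), patient, rec_id,
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_num(256 * (ns + 1)), edf_field("", 44),
    edf_num(n_rec), edf_num(1), edf_field(ns, 4),
    paste(vapply(labels, edf_field, character(1), width = 16), collapse = ""),
    strrep(edf_field("synthetic", 80), ns),
    strrep(edf_field("uV", 8), ns),
    paste(vapply(-pmaxs, edf_num, character(1)), collapse = ""),
    paste(vapply(pmaxs, edf_num, character(1)), collapse = ""),
    strrep(edf_num(-32768), ns),
    strrep(edf_num(32767), ns),
    strrep(edf_field("HP:none LP:none", 80), ns),
    strrep(edf_num(fs), ns),
    strrep(edf_field("", 32), ns)
  ), con, eos = NULL)

  dig <- lapply(seq_along(chans), function(i) {
    scale <- (2 * pmaxs[i]) / 65535
    d <- as.integer(round((chans[[i]] + pmaxs[i]) / scale) - 32768L)
    pmax(pmin(d, 32767L), -32768L)
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_along(dig)) {
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path Path to an EDF/EDF+ file with uniformly sampled channels.
#' @param expected_channels Internal channel names that must be present
#'   (any of `eeg_frontal`, `eeg_parietal`, `emg`, or raw EDF labels).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path,
                           expected_channels = c("eeg_frontal", "emg")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256) stopf("truncated EDF header")
  fld <- function(from, len) trimws(substr(hdr, from, from + len - 1))
  patient <- fld(9, 80)
  rec_id <- fld(89, 80)
  n_rec <- as.integer(fld(237, 8))
  rec_dur <- as.numeric(fld(245, 8))
  ns <- as.integer(fld(253, 4))
  if (is.na(ns) || ns < 1) stopf("unreadable EDF: bad signal count")

  sig_hdr <- readChar(con, ns * 256, useBytes = TRUE)
  sfld <- function(offset, len, i) {
    start <- offset * ns + (i - 1) * len + 1
    trimws(substr(sig_hdr, start, start + len - 1))
  }
  labels <- vapply(seq_len(ns), function(i) sfld(0, 16, i), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) sfld(16 + 80 + 8, 8, i), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) sfld(16 + 80 + 8 + 8, 8, i), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) sfld(16 + 80 + 8 + 16, 8, i), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) sfld(16 + 80 + 8 + 24, 8, i), character(1)))
  nsamp <- as.integer(vapply(seq_len(ns), function(i) sfld(216, 8, i), character(1)))

  data <- lapply(seq_len(ns), function(i) numeric(n_rec * nsamp[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = nsamp[i], size = 2,
                     signed = TRUE, endian = "little")
      if (length(raw) < nsamp[i]) stopf("truncated EDF data record %d", r)
      scale <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
      data[[i]][((r - 1) * nsamp[i] + 1):(r * nsamp[i])] <-
        pmin_[i] + (raw - dmin_[i]) * scale
    }
  }

  internal <- unname(EDF_LABEL_MAP[labels])
  internal[is.na(internal)] <- labels[is.na(internal)]
  names(data) <- internal
  missing <- setdiff(expected_channels, c(internal, labels))
  if (length(missing)) {
    stopf("missing channel(s): %s", paste(missing, collapse = ", "))
  }
  fs <- unique(nsamp / rec_dur)
  if (length(fs) != 1) stopf("non-uniform sampling rate across channels")

  parse_kv <- function(key) {
    m <- regmatches(rec_id, regexec(paste0(key, "=([^ ]+)"), rec_id))[[1]]
    if (length(m) == 2 && m[2] != "NA") m[2] else NA_character_
  }
  structure(list(
    channels = data, fs = fs, t0 = 0,
    meta = list(subject = if (nzchar(patient)) patient else NA_character_,
                genotype = parse_kv("genotype"),
                treatment = parse_kv("treatment"),
                injection_time_s = suppressWarnings(
                  as.numeric(parse_kv("injection_s"))))),
    class = "eeg_recording")
}

#' Read an artifact mask from a TSV file
#'
#' The table must have columns `epoch_index` (0-based) and `is_artifact`;
#' epochs absent from the table default to non-artifact so that sparse
#' (artifact-only) tables are valid.
#'
#' @param path TSV path.
#' @param n_epochs Total number of 4-s epochs in the recording.
#' @return An [artifact_mask()] with exactly `n_epochs` entries.
#' @export
read_artifact_mask <- function(path, n_epochs) {
  tab <- utils::read.delim(path, sep = "\t")
  if (!all(c("epoch_index", "is_artifact") %in% names(tab))) {
    stopf("mask table must have columns epoch_index, is_artifact")
  }
  if (anyDuplicated(tab$epoch_index)) stopf("duplicate epoch_index in mask")
  if (nrow(tab) && any(tab$epoch_index < 0 | tab$epoch_index >= n_epochs)) {
    stopf("epoch_index out of range [0, %d)", n_epochs)
  }
  flags <- rep(FALSE, n_epochs)
  flags[tab$epoch_index + 1L] <- as.logical(tab$is_artifact)
  artifact_mask(flags)
}

#' @rdname read_artifact_mask
#' @param mask An [artifact_mask()].
#' @export
write_artifact_mask <- function(mask, path) {
  utils::write.table(as.data.frame(mask)[, c("epoch_index", "is_artifact")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a study design table
#'
#' @param path TSV with columns `subject`, `genotype`, `treatment` and
#'   optionally `injection_time_s`.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, sep = "\t", colClasses = c(subject = "character"))
  need <- c("subject", "genotype", "treatment")
  if (!all(need %in% names(d))) {
    stopf("design table must have columns %s", paste(need, collapse = ", "))
  }
  d
}

#' Session layout for a pharmaco-EEG treatment recording
#'
#' The standard session is 1 h of pretreatment EEG followed by 5 h of
#' post-treatment EEG, with the injection at the boundary.
#'
#' @param pre_start,injection_time,post_end Seconds from recording start.
#' @return A `session_layout` list.
#' @export
session_layout <- function(pre_start = 0, injection_time = 3600,
                           post_end = 21600) {
  if (!(pre_start < injection_time && injection_time < post_end)) {
    stopf("need pre_start < injection_time < post_end")
  }
  structure(list(pre_start = pre_start, injection_time = injection_time,
                 post_end = post_end), class = "session_layout")
}

#' Validate a recording against a session layout
#'
#' Returns diagnostics rather than raising: truncated pre/post windows are
#' warnings, non-finite samples and rate problems are errors.
#'
#' @param recording An `eeg_recording`.
#' @param layout A [session_layout()].
#' @return data.frame with columns `level` ("warning"/"error") and
#'   `message`; zero rows for a conforming session.
#' @export
validate_session <- function(recording, layout = session_layout()) {
  out <- data.frame(level = character(0), message = character(0))
  add <- function(level, msg) {
    rbind(out, data.frame(level = level, message = msg))
  }
  if (!is.numeric(recording$fs) || recording$fs <= 0) {
    out <- add("error", "non-positive sampling rate")
    return(out)
  }
  lens <- vapply(recording$channels, length, integer(1))
  if (length(unique(lens)) != 1) {
    out <- add("error", "channels have unequal lengths")
  }
  for (ch in names(recording$channels)) {
    if (any(!is.finite(recording$channels[[ch]]))) {
      out <- add("error", sprintf("non-finite samples in channel %s", ch))
    }
  }
  duration <- max(lens) / recording$fs
  pre_expected <- layout$injection_time - layout$pre_start
  post_expected <- layout$post_end - layout$injection_time
  inj <- recording$meta$injection_time_s
  inj <- if (is.null(inj) || is.na(inj)) layout$injection_time else inj
  if (inj - layout$pre_start < pre_expected - 1e-9) {
    out <- add("warning", sprintf(
      "pretreatment window truncated: %.0f s instead of %.0f s",
      inj - layout$pre_start, pre_expected))
  }
  if (duration - inj < post_expected - 1e-9) {
    out <- add("warning", sprintf(
      "post-treatment window truncated: %.0f s instead of %.0f s",
      duration - inj, post_expected))
  }
  out
}
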