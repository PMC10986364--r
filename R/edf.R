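# Minimal European Data Format (EDF) input/output. Covers the plain EDF
# profile this package needs: identical sampling rate on every signal,
# 1-second data records, 16-bit little-endian samples with per-signal
# physical scaling. Seizure onsets travel in a plain-text sidecar
# `<file>.seizures.tsv` (columns subject_id, onset_s) because EDF proper has
# no annotation channel.

pad_field <- function(x, width) {
  s <- sprintf("%-*s", width, as.character(x))
  substr(s, 1, width)
}

#' Write a recording to an EDF file
#'
#' Physical units are microvolts; the digital range is the full 16-bit span
#' scaled to the recording's observed amplitude range, so round-tripping
#' quantises values to about 1/65536 of that range. Seizure onsets are written
#' to `<path>.seizures.tsv`.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  ns <- nrow(rec$signal)
  fs <- rec$fs
  if (fs != round(fs)) stopf("EDF writer requires an integer sampling rate")
  n_rec <- floor(ncol(rec$signal) / fs)
  if (n_rec < 1) stopf("recording shorter than one 1-s EDF record")
  x <- rec$signal[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  scale <- (pmax_ - pmin_) / (dmax - dmin)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id, 80),
    pad_field("synthetic EEG", 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 + 256 * ns, 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    vapply(rec$channel_names, pad_field, "", width = 16),
    rep(pad_field("", 80), ns),
    rep(pad_field("uV", 8), ns),
    vapply(sprintf("%.8g", pmin_), pad_field, "", width = 8),
    vapply(sprintf("%.8g", pmax_), pad_field, "", width = 8),
    rep(pad_field(dmin, 8), ns),
    rep(pad_field(dmax, 8), ns),
    rep(pad_field("", 80), ns),
    rep(pad_field(fs, 8), ns),
    rep(pad_field("", 32), ns))
  writeChar(paste0(fields, collapse = ""), con, eos = NULL)

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((x[s, idx] - pmin_[s]) / scale[s]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  write_seizure_sidecar(rec, paste0(path, ".seizures.tsv"))
  invisible(path)
}

#' Read an EDF file written in the plain profile
#'
#' Requires every signal to share one sampling rate. If a
#' `<path>.seizures.tsv` sidecar exists its onsets are attached.
#'
#' @param path EDF file path.
#' @return A [recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                   # version
  subject_id <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)           # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) stopf("EDF reader requires one sampling rate across signals")
  fs <- spr[1] / rec_dur
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                     endian = "little")
      sig[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        (dig - dmin[s]) * scale[s] + pmin_[s]
    }
  }
  onsets <- numeric(0)
  sidecar <- paste0(path, ".seizures.tsv")
  if (file.exists(sidecar)) onsets <- read_seizure_sidecar(sidecar)$onset_s
  recording(sig, labels, fs, onsets, subject_id)
}

#' Write/read the seizure-onset sidecar TSV
#'
#' @param rec A [recording()].
#' @param path TSV path.
#' @return For the writer, `path` invisibly; for the reader, a data.frame with
#'   columns `subject_id` and `onset_s`.
#' @export
write_seizure_sidecar <- function(rec, path) {
  df <- data.frame(subject_id = rep(rec$subject_id, length(rec$onsets_s)),
                   onset_s = rec$onsets_s)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_seizure_sidecar
#' @export
read_seizure_sidecar <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "numeric"))
}
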