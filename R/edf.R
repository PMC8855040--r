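# Minimal European Data Format (EDF) I/O: fixed-width ASCII header plus
# 16-bit little-endian samples, enough to round-trip the cohorts this
# package generates and to ingest plain continuous EDF recordings.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording as an EDF file
#'
#' One EDF signal per channel, digitized to 16 bits against a symmetric
#' physical range spanning the channel's amplitude (quantization error below
#' 2^-15 of the range). Record duration is 1 s when the length divides
#' evenly, otherwise a single record holding the whole signal.
#'
#' @param recording an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$samples
  ns <- nrow(x)
  n <- ncol(x)
  fs <- recording$sampling_rate
  if (n %% round(fs) == 0 && abs(fs - round(fs)) < 1e-9) {
    n_rec <- n %/% round(fs)
    spr <- round(fs)
    rec_dur <- 1
  } else {
    n_rec <- 1L
    spr <- n
    rec_dur <- n / fs
  }
  pm <- apply(x, 1, function(ch) max(abs(ch), 1e-6))
  dig <- t(vapply(seq_len(ns), function(i) {
    as.integer(round(x[i, ] / pm[i] * 32767))
  }, integer(n)))

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr(recording$subject_id, 80)
  wr(paste("group", recording$group), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 * (1 + ns), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(format(rec_dur, digits = 7), 8)
  wr(ns, 4)
  for (lab in recording$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(-pm[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(format(pm[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(-32767, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      writeBin(dig[i, idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports continuous EDF with a common sampling rate across signals.
#'
#' @param path EDF file path.
#' @return an `eeg_recording` (group `NA`; subject id from the patient field).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8) # version
  subject_id <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8) # unit
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) {
    stop("signals with differing sampling rates are not supported")
  }
  out <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2,
                   endian = "little", signed = TRUE)
      scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      out[i, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        phys_min[i] + (d - dig_min[i]) * scale
    }
  }
  new_recording(out, spr[1] / rec_dur, channel_labels = labels,
                subject_id = if (nzchar(subject_id)) subject_id else "subject")
}
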