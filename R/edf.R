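# Minimal European Data Format (EDF) reader and writer.
#
# Covers the plain-EDF subset this package needs: 16-bit samples, one
# record per second, identical sampling rate for every signal.  Field
# layout follows the published EDF header specification (256-byte fixed
# header + 256 bytes per signal, field-major signal headers).

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = max(1L, width - 2L), width = 0L)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

write_edf <- function(recording, path) {
  fs <- recording$fs
  if (fs != round(fs))
    stop("EDF writer requires an integer sampling rate")
  n <- n_samples(recording)
  if (n < 1) stop("cannot write an empty recording (0 samples)")
  if (n %% fs != 0)
    stop("EDF writer requires a whole number of seconds of data")
  n_rec <- n %/% fs
  sig <- cbind(recording$signals, TRIGGER = recording$trigger)
  labels <- c(recording$channel_labels, "TRIGGER")
  ns <- ncol(sig)

  pmin <- apply(sig, 2, min)
  pmax <- apply(sig, 2, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(recording$subject_id, 80),
    edf_pad(recording$recording_id, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4),
    paste(vapply(labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(vapply(c(rep("uV", ns - 1), ""), edf_pad, "", width = 8), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- matrix(0L, nrow = n, ncol = ns)
  for (j in seq_len(ns)) {
    d <- round((sig[, j] - pmin[j]) * scale[j] + dmin)
    dig[, j] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  # record-major, signal-major within record
  out <- integer(n * ns)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (j in seq_len(ns)) {
      out[(pos + 1L):(pos + fs)] <- dig[rows, j]
      pos <- pos + fs
    }
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) {
    raw <- readChar(con, w, useBytes = TRUE)
    trimws(raw)
  }
  version <- rd(8)
  patient <- rd(80)
  rec_field <- rd(80)
  rd(8); rd(8)                       # date, time
  rd(8)                              # header bytes
  rd(44)                             # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  field <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- field(16)
  field(80)                          # transducer
  field(8)                           # physical dimension
  pmin <- as.numeric(field(8))
  pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8))
  dmax <- as.numeric(field(8))
  field(80)                          # prefiltering
  spr <- as.integer(field(8))
  field(32)                          # reserved
  list(version = version, patient = patient, recording = rec_field,
       n_rec = n_rec, rec_dur = rec_dur, ns = ns, labels = labels,
       pmin = pmin, pmax = pmax, dmin = dmin, dmax = dmax, spr = spr)
}

read_edf <- function(path, trigger_label = "TRIGGER") {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (length(unique(h$spr)) != 1)
    stop("EDF reader supports a single sampling rate across signals")
  fs <- h$spr[1] / h$rec_dur
  n <- h$n_rec * h$spr[1]
  raw <- readBin(con, "integer", n = n * h$ns, size = 2L,
                 endian = "little", signed = TRUE)
  if (length(raw) < n * h$ns) stop("EDF file truncated")
  sig <- matrix(0, nrow = n, ncol = h$ns)
  pos <- 0L
  for (r in seq_len(h$n_rec)) {
    rows <- ((r - 1L) * h$spr[1] + 1L):(r * h$spr[1])
    for (j in seq_len(h$ns)) {
      sig[rows, j] <- raw[(pos + 1L):(pos + h$spr[1])]
      pos <- pos + h$spr[1]
    }
  }
  for (j in seq_len(h$ns)) {
    sig[, j] <- (sig[, j] - h$dmin[j]) / (h$dmax[j] - h$dmin[j]) *
      (h$pmax[j] - h$pmin[j]) + h$pmin[j]
  }
  trig_idx <- which(toupper(h$labels) == toupper(trigger_label))
  if (length(trig_idx) != 1)
    stop(sprintf("missing trigger channel '%s' in EDF signal labels", trigger_label))
  eeg_recording(sig[, -trig_idx, drop = FALSE], fs = fs,
                channel_labels = h$labels[-trig_idx],
                trigger = sig[, trig_idx],
                subject_id = if (nzchar(h$patient)) h$patient else "S01",
                recording_id = if (nzchar(h$recording)) h$recording else "R1")
}
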