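#' Read a recording from disk
#'
#' Two dialects are supported.  `"csv"` is the package's self-describing
#' plain-text dialect: a first comment line `# fs=<Hz>` (optionally also
#' `subject=` and `recording=` fields), then a header row of channel
#' labels whose last column is the trigger channel (`TRIGGER`), then one
#' row per sample.  `"edf"` is the European Data Format; the trigger is
#' the signal whose label matches `trigger_label`.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"edf"`.
#' @param trigger_label label identifying the trigger channel.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, dialect = c("csv", "edf"),
                           trigger_label = "TRIGGER") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         csv = read_recording_csv(path, trigger_label),
         edf = read_edf(path, trigger_label))
}

read_recording_csv <- function(path, trigger_label = "TRIGGER") {
  first <- readLines(path, n = 1L)
  if (!grepl("^#", first))
    stop("CSV dialect requires a leading '# fs=<Hz>' line")
  meta_get <- function(key, default) {
    m <- regmatches(first, regexec(paste0(key, "=([^ ,#]+)"), first))[[1]]
    if (length(m) == 2) m[2] else default
  }
  fs <- as.numeric(meta_get("fs", NA))
  if (!is.finite(fs) || fs <= 0) stop("CSV header line must carry fs=<Hz>")
  nf <- utils::count.fields(path, sep = ",", comment.char = "#")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1)
    stop("ragged CSV rows: field counts vary (",
         paste(unique(nf), collapse = ", "), ")")
  dt <- data.table::fread(path, skip = 1L, header = TRUE, sep = ",",
                          fill = FALSE, data.table = FALSE)
  if (anyNA(dt))
    stop("ragged or non-numeric CSV rows (missing values after parsing)")
  labels <- names(dt)
  trig_idx <- which(toupper(labels) == toupper(trigger_label))
  if (length(trig_idx) != 1)
    stop(sprintf("missing trigger channel '%s' in CSV header", trigger_label))
  eeg_recording(as.matrix(dt[, -trig_idx, drop = FALSE]), fs = fs,
                channel_labels = labels[-trig_idx],
                trigger = dt[[trig_idx]],
                subject_id = meta_get("subject", "S01"),
                recording_id = meta_get("recording", "R1"))
}

#' Write a recording to disk
#'
#' Round-trips losslessly through the CSV dialect and to 16-bit
#' quantization through EDF.
#'
#' @param recording an [eeg_recording()].
#' @param path destination file path.
#' @param dialect `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, dialect = c("csv", "edf")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(recording, "eeg_recording"))
  if (n_samples(recording) == 0)
    stop("cannot write an empty recording (0 samples)")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  switch(dialect,
         csv = {
           hdr <- sprintf("# fs=%.10g subject=%s recording=%s",
                          recording$fs, recording$subject_id,
                          recording$recording_id)
           writeLines(hdr, path)
           df <- as.data.frame(recording$signals)
           df$TRIGGER <- recording$trigger
           data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
         },
         edf = write_edf(recording, path))
  invisible(path)
}

#' Detect light-sensor trigger pulses
#'
#' A pulse is a maximal run of samples at or above a threshold set as a
#' fraction of the trigger's dynamic range, lasting at least
#' `min_width_s`.  Because the threshold is relative, detection is
#' invariant to affine rescaling of the trigger.
#'
#' @param trigger numeric vector (arbitrary units).
#' @param fs sampling rate in Hz.
#' @param threshold fraction of the dynamic range (default 0.5).
#' @param min_width_s minimum pulse width in seconds (default 0.25,
#'   half the nominal 0.5 s on-screen square).
#' @return data.frame with integer columns `onset` and `offset`
#'   (0-based, half-open intervals), sorted by onset.  Empty if no
#'   pulse is found.
#' @export
detect_trigger_pulses <- function(trigger, fs, threshold = 0.5,
                                  min_width_s = 0.25) {
  if (length(trigger) == 0) stop("empty trigger channel")
  lo <- min(trigger); hi <- max(trigger)
  empty <- data.frame(onset = integer(0), offset = integer(0))
  if (hi - lo <= 0) return(empty)
  above <- trigger >= lo + threshold * (hi - lo)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width_s * fs
  if (!any(keep)) return(empty)
  data.frame(onset = starts[keep] - 1L, offset = ends[keep])
}

#' Segment a recording into labeled task epochs
#'
#' Uses detected trigger pulses to cut the recording into one epoch per
#' protocol task.  In `"shared"` boundary mode back-to-back tasks share
#' a boundary pulse, so `n_tasks + 1` pulses are expected and epoch *k*
#' spans pulse-onset *k* to pulse-onset *k + 1*.  In `"paired"` mode
#' each task has its own start and end pulse (`2 * n_tasks` pulses) and
#' epoch *k* spans the onset of pulse *2k - 1* to the offset of pulse
#' *2k*.
#'
#' @param recording an [eeg_recording()].
#' @param pulses data.frame from [detect_trigger_pulses()].
#' @param protocol an [eeg_protocol()].
#' @param boundary_mode `"shared"` (default) or `"paired"`.
#' @param duration_tol relative deviation from the protocol task
#'   duration above which an epoch is rejected (default 0.1).
#' @return list of [task_epoch()] objects in protocol order.
#' @export
segment_tasks <- function(recording, pulses, protocol = default_protocol(),
                          boundary_mode = c("shared", "paired"),
                          duration_tol = 0.1) {
  boundary_mode <- match.arg(boundary_mode)
  n_tasks <- nrow(protocol$tasks)
  need <- if (boundary_mode == "shared") n_tasks + 1L else 2L * n_tasks
  if (nrow(pulses) != need)
    stop(sprintf("pulse-count mismatch: expected %d pulses for %d tasks in %s mode, found %d",
                 need, n_tasks, boundary_mode, nrow(pulses)))
  fs <- recording$fs
  spans <- if (boundary_mode == "shared") {
    cbind(pulses$onset[seq_len(n_tasks)], pulses$onset[seq_len(n_tasks) + 1L])
  } else {
    cbind(pulses$onset[2L * seq_len(n_tasks) - 1L],
          pulses$offset[2L * seq_len(n_tasks)])
  }
  expect <- protocol$task_duration_s * fs
  epochs <- vector("list", n_tasks)
  for (k in seq_len(n_tasks)) {
    dur <- spans[k, 2] - spans[k, 1]
    if (abs(dur - expect) > duration_tol * expect)
      stop(sprintf("epoch %d deviates from the %g s task duration (got %.2f s)",
                   k, protocol$task_duration_s, dur / fs))
    idx <- (spans[k, 1] + 1L):spans[k, 2]   # 0-based half-open -> 1-based rows
    tk <- protocol$tasks[k, ]
    epochs[[k]] <- task_epoch(recording$signals[idx, , drop = FALSE], fs,
                              tk$region, tk$side, tk$mode,
                              recording$subject_id, recording$recording_id, k)
  }
  epochs
}
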