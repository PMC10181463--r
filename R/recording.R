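#' Multichannel EEG recording
#'
#' Container for one continuous recording: an n-samples x n-channels
#' signal matrix in microvolts, an auxiliary light-sensor trigger
#' channel of the same length (arbitrary units), the sampling rate and
#' identifiers.
#'
#' @param signals numeric matrix, samples in rows, one column per EEG
#'   channel (microvolts).  A vector is treated as a single channel.
#' @param fs sampling rate in Hz (default 512).
#' @param channel_labels character vector of unique channel names
#'   (10-20 positions for multichannel montages, `"FP1"` for the
#'   single-channel one).
#' @param trigger numeric vector, same length as the signals.
#' @param subject_id,recording_id identifiers carried through the
#'   pipeline as provenance.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signals, fs = 512, channel_labels = NULL,
                          trigger = NULL, subject_id = "S01",
                          recording_id = "R1") {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1)
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  n <- nrow(signals)
  if (is.null(channel_labels))
    channel_labels <- colnames(signals)
  if (is.null(channel_labels))
    channel_labels <- paste0("CH", seq_len(ncol(signals)))
  if (length(channel_labels) != ncol(signals))
    stop("channel_labels length must match the number of signal columns")
  if (anyDuplicated(channel_labels))
    stop("channel_labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(trigger)) trigger <- numeric(n)
  trigger <- as.numeric(trigger)
  if (length(trigger) != n)
    stop(sprintf("ragged lengths: %d trigger samples vs %d signal samples",
                 length(trigger), n))
  colnames(signals) <- channel_labels
  structure(list(signals = signals, fs = fs,
                 channel_labels = channel_labels, trigger = trigger,
                 subject_id = as.character(subject_id),
                 recording_id = as.character(recording_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d channels x %d samples (%.1f s at %g Hz)\n",
              x$subject_id, x$recording_id, ncol(x$signals), nrow(x$signals),
              nrow(x$signals) / x$fs, x$fs))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param recording an `eeg_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(recording) nrow(recording$signals)

#' One labeled task segment of a recording
#'
#' @param signals numeric matrix (samples x channels) in microvolts.
#' @param fs sampling rate in Hz.
#' @param region,side,mode the task's class factors.
#' @param subject_id,recording_id,task_index provenance.
#' @return An object of class `task_epoch`.
#' @export
task_epoch <- function(signals, fs, region, side, mode,
                       subject_id = "S01", recording_id = "R1",
                       task_index = 1L) {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1)
  stopifnot(region %in% c("hand", "ankle"), side %in% c("left", "right"),
            mode %in% c("real", "imagery"), fs > 0)
  structure(list(signals = as.matrix(signals), fs = fs,
                 region = region, side = side, mode = mode,
                 label = task_label(region, side, mode),
                 subject_id = as.character(subject_id),
                 recording_id = as.character(recording_id),
                 task_index = as.integer(task_index)),
            class = "task_epoch")
}

#' @export
print.task_epoch <- function(x, ...) {
  cat(sprintf("<task_epoch> %s (task %d of %s/%s): %d ch x %d samples (%.2f s)\n",
              x$label, x$task_index, x$subject_id, x$recording_id,
              ncol(x$signals), nrow(x$signals), nrow(x$signals) / x$fs))
  invisible(x)
}
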