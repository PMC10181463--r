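#' Task protocol
#'
#' A protocol is the ordered list of tasks a subject performs in one
#' recording session.  Each task is described by the body region moved
#' (`hand` or `ankle`), the body side (`left` or `right`) and the mode
#' (`real` movement or motor `imagery`).  The default protocol is the
#' eight-task sequence used throughout the package: imagery right hand,
#' real right hand, imagery left hand, real left hand, imagery right
#' ankle, real right ankle, imagery left ankle, real left ankle, each
#' lasting 30 s with no interval between tasks.
#'
#' @param tasks data.frame with columns `region`, `side`, `mode`.
#' @param task_duration_s duration of each task in seconds.
#' @return An object of class `eeg_protocol`: a list with elements
#'   `tasks` (data.frame with an added `label` column) and
#'   `task_duration_s`.
#' @export
eeg_protocol <- function(tasks, task_duration_s = 30) {
  stopifnot(is.data.frame(tasks), nrow(tasks) >= 1)
  need <- c("region", "side", "mode")
  if (!all(need %in% names(tasks)))
    stop("protocol tasks need columns region, side, mode")
  if (!all(tasks$region %in% c("hand", "ankle")))
    stop("region must be 'hand' or 'ankle'")
  if (!all(tasks$side %in% c("left", "right")))
    stop("side must be 'left' or 'right'")
  if (!all(tasks$mode %in% c("real", "imagery")))
    stop("mode must be 'real' or 'imagery'")
  if (!is.numeric(task_duration_s) || task_duration_s <= 0)
    stop("task_duration_s must be a positive number")
  tasks <- tasks[, need]
  tasks$label <- task_label(tasks$region, tasks$side, tasks$mode)
  structure(list(tasks = tasks, task_duration_s = task_duration_s),
            class = "eeg_protocol")
}

#' Default eight-task protocol
#'
#' @param task_duration_s task duration in seconds (default 30).
#' @return An `eeg_protocol` with the standard task orientation order.
#' @export
default_protocol <- function(task_duration_s = 30) {
  tasks <- data.frame(
    region = c("hand", "hand", "hand", "hand", "ankle", "ankle", "ankle", "ankle"),
    side   = c("right", "right", "left", "left", "right", "right", "left", "left"),
    mode   = c("imagery", "real", "imagery", "real", "imagery", "real", "imagery", "real"),
    stringsAsFactors = FALSE
  )
  eeg_protocol(tasks, task_duration_s)
}

#' Compose a class label from its three factors
#'
#' Labels have the form `"<mode>-<side>-<region>"`, e.g.
#' `"imagery-left-hand"`.
#'
#' @param region,side,mode character vectors.
#' @return character vector of labels.
#' @export
task_label <- function(region, side, mode) {
  paste(mode, side, region, sep = "-")
}

#' The eight activity classes in protocol order
#'
#' Class order is fixed by the default protocol and is used for every
#' confusion matrix produced by the package.
#'
#' @param protocol an `eeg_protocol`; default the standard one.
#' @return character vector of class labels.
#' @export
protocol_classes <- function(protocol = default_protocol()) {
  protocol$tasks$label
}

#' @export
print.eeg_protocol <- function(x, ...) {
  cat(sprintf("<eeg_protocol> %d tasks x %g s\n", nrow(x$tasks), x$task_duration_s))
  print(x$tasks, row.names = FALSE)
  invisible(x)
}
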