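#' Statistical-moment feature specification
#'
#' The classifier's features are the statistical moments of orders 1 to
#' 10 of each channel in each analysis window.  Three conventions are
#' supported: `raw` (mean of `x^k`), `central` (mean of `(x - mean)^k`,
#' the default) and `standardized` (central moment divided by the
#' k/2 power of the variance).  Order 1 is always the sample mean.
#'
#' `normalize = "recording"` (the default used by the pipeline) z-scores
#' each channel once over the whole filtered recording before windows
#' are cut, so features are on a sane numeric scale while per-window
#' differences in dispersion remain informative.  `"none"` computes
#' moments of the literal microvolt signal.
#'
#' @param orders integer vector of moment orders within 1..10.
#' @param kind `"central"`, `"raw"` or `"standardized"`.
#' @param normalize `"recording"` or `"none"`; applied by
#'   [extract_features()], not by [statistical_moments()] itself.
#' @return An object of class `moment_spec`.
#' @export
moment_spec <- function(orders = 1:10,
                        kind = c("central", "raw", "standardized"),
                        normalize = c("recording", "none")) {
  kind <- match.arg(kind)
  normalize <- match.arg(normalize)
  orders <- as.integer(orders)
  if (length(orders) == 0 || any(orders < 1L | orders > 10L))
    stop("orders must be a nonempty subset of 1..10")
  if (anyDuplicated(orders)) stop("orders must be unique")
  structure(list(orders = orders, kind = kind, normalize = normalize),
            class = "moment_spec")
}

#' Statistical moments of a single-channel window
#'
#' @param x numeric vector of at least 2 samples.
#' @param spec a [moment_spec()].
#' @return named numeric vector, one value per requested order
#'   (`m<order>`).
#' @export
statistical_moments <- function(x, spec = moment_spec()) {
  n <- length(x)
  if (n < 2) stop("window must have at least 2 samples")
  mu <- mean(x)
  kmax <- max(spec$orders)
  vals <- numeric(kmax)
  vals[1] <- mu
  if (kmax >= 2) {
    if (spec$kind == "raw") {
      p <- x
      for (k in 2:kmax) {
        p <- p * x
        vals[k] <- mean(p)
      }
    } else {
      d <- x - mu
      m2 <- mean(d * d)
      if (spec$kind == "standardized" && m2 <= 0)
        stop("standardized moments undefined for zero-variance window")
      p <- d
      for (k in 2:kmax) {
        p <- p * d
        vals[k] <- mean(p)
      }
      if (spec$kind == "standardized")
        vals[2:kmax] <- vals[2:kmax] / m2^((2:kmax) / 2)
    }
  }
  out <- vals[spec$orders]
  names(out) <- paste0("m", spec$orders)
  out
}

#' Assemble a feature table from analysis windows
#'
#' One row per window; feature columns are ordered channel-major then
#' by moment order and named `"<channel>_m<order>"`.  Class label and
#' provenance (subject, recording, task, window) are carried as leading
#' columns.
#'
#' @param windows list of windows from [window_epoch()].
#' @param spec a [moment_spec()].
#' @return data.frame of class `feature_table`.
#' @export
build_feature_table <- function(windows, spec = moment_spec()) {
  if (length(windows) == 0) stop("empty window list: refusing to build an empty feature table")
  ch <- colnames(windows[[1]]$signals)
  if (is.null(ch)) ch <- paste0("CH", seq_len(ncol(windows[[1]]$signals)))
  same <- vapply(windows, function(w) {
    identical(ncol(w$signals), length(ch)) &&
      (is.null(colnames(w$signals)) || identical(colnames(w$signals), ch))
  }, TRUE)
  if (!all(same)) stop("heterogeneous channel sets across windows")
  n_ord <- length(spec$orders)
  feat <- matrix(NA_real_, nrow = length(windows), ncol = length(ch) * n_ord)
  colnames(feat) <- as.vector(vapply(ch, function(c)
    paste0(c, "_m", spec$orders), character(n_ord)))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    for (j in seq_along(ch)) {
      feat[i, ((j - 1L) * n_ord + 1L):(j * n_ord)] <-
        statistical_moments(w$signals[, j], spec)
    }
  }
  meta <- data.frame(
    subject_id   = vapply(windows, `[[`, "", "subject_id"),
    recording_id = vapply(windows, `[[`, "", "recording_id"),
    task_index   = vapply(windows, `[[`, 1L, "task_index"),
    window_index = vapply(windows, `[[`, 1L, "window_index"),
    region = vapply(windows, `[[`, "", "region"),
    side   = vapply(windows, `[[`, "", "side"),
    mode   = vapply(windows, `[[`, "", "mode"),
    label  = vapply(windows, `[[`, "", "label"),
    stringsAsFactors = FALSE
  )
  out <- cbind(meta, as.data.frame(feat))
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Names of the feature columns of a feature table
#'
#' @param table a feature table.
#' @return character vector of `"<channel>_m<order>"` column names.
#' @export
feature_columns <- function(table) {
  grep("_m[0-9]+$", names(table), value = TRUE)
}
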