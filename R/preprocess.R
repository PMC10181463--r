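#' Band-pass filter specification
#'
#' The preprocessing filter is a 3rd-order Butterworth band-pass from
#' 0.5 to 59 Hz: the low edge removes baseline drift (eye movement,
#' breathing, sweat), the high edge removes powerline hum while keeping
#' the delta-to-low-gamma brain rhythms.  Applied forward-backward
#' (`zero_phase`, the default) the effective magnitude response is the
#' squared one-pass response and no group delay is introduced.
#'
#' @param low_hz high-pass edge in Hz (default 0.5).
#' @param high_hz low-pass edge in Hz (default 59).
#' @param order filter order (default 3).
#' @param application `"zero_phase"` (forward-backward, default) or
#'   `"causal"` (single forward pass).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 59, order = 3,
                        application = c("zero_phase", "causal")) {
  application <- match.arg(application)
  if (!(low_hz > 0 && high_hz > low_hz))
    stop("need 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 application = application),
            class = "filter_spec")
}

butter_coefs <- function(spec, fs) {
  if (spec$high_hz >= fs / 2)
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency (%g)",
                 spec$high_hz, fs / 2))
  signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                 type = "pass")
}

#' Band-pass filter a multichannel signal
#'
#' Each channel is filtered independently.  See [filter_spec()].
#'
#' @param signals numeric matrix (samples x channels) or vector.
#' @param fs sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return filtered signals, same shape as the input.
#' @export
bandpass_filter <- function(signals, fs, spec = filter_spec()) {
  vec <- is.vector(signals)
  if (vec) signals <- matrix(signals, ncol = 1)
  bf <- butter_coefs(spec, fs)
  n <- nrow(signals)
  # odd extension at both ends tames the forward-backward edge
  # transients (notably for signals with a DC offset)
  pad <- min(n - 1L, round(fs))
  out <- signals
  for (j in seq_len(ncol(signals))) {
    x <- signals[, j]
    if (spec$application == "zero_phase") {
      ext <- c(2 * x[1] - x[(pad + 1L):2],
               x,
               2 * x[n] - x[(n - 1L):(n - pad)])
      y <- signal::filtfilt(bf, ext)
      out[, j] <- y[(pad + 1L):(pad + n)]
    } else {
      out[, j] <- as.numeric(signal::filter(bf, x))
    }
  }
  if (vec) out <- out[, 1]
  out
}

#' Magnitude response of the designed filter
#'
#' Evaluates the designed digital filter's own frequency response at
#' the requested frequencies; for `zero_phase` application the
#' magnitude is squared (forward-backward).  Used as the oracle for the
#' filter's gain/attenuation contracts.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz.
#' @param freqs_hz frequencies at which to evaluate, in Hz.
#' @return numeric vector of magnitude gains (linear scale).
#' @export
filter_response <- function(spec, fs, freqs_hz) {
  bf <- butter_coefs(spec, fs)
  h <- signal::freqz(bf, n = 8192, Fs = fs)
  mag <- stats::approx(h$f, abs(h$h), xout = freqs_hz)$y
  if (spec$application == "zero_phase") mag^2 else mag
}

#' Trim the transient edges of a task epoch
#'
#' Discards the first and last `trim_s` seconds of an epoch, keeping
#' the central portion (5 s + 5 s trimmed from a 30 s task leaves the
#' central 20 s).
#'
#' @param epoch a [task_epoch()].
#' @param trim_s seconds to discard at each end (default 5).
#' @return the trimmed [task_epoch()], label preserved.
#' @export
trim_epoch <- function(epoch, trim_s = 5) {
  stopifnot(inherits(epoch, "task_epoch"))
  n <- nrow(epoch$signals)
  cut <- round(trim_s * epoch$fs)
  if (n <= 2 * cut)
    stop(sprintf("epoch too short to trim %g s at each end (%.2f s total)",
                 trim_s, n / epoch$fs))
  if (cut > 0)
    epoch$signals <- epoch$signals[(cut + 1L):(n - cut), , drop = FALSE]
  epoch
}

#' Cut an epoch into fixed-length analysis windows
#'
#' Windows inherit the epoch's label and provenance; each becomes one
#' classification example.  With window length `w` samples and step
#' `w * (1 - overlap_frac)`, the number of windows is
#' `floor((N - w) / step) + 1`.
#'
#' @param epoch a [task_epoch()].
#' @param win_len_s window length in seconds (default 2).
#' @param overlap_frac fractional overlap between consecutive windows
#'   in `[0, 1)` (default 0.5).
#' @return list of window objects (class `eeg_window`), each carrying
#'   `signals`, `fs`, the class factors and provenance.
#' @export
window_epoch <- function(epoch, win_len_s = 2, overlap_frac = 0.5) {
  stopifnot(inherits(epoch, "task_epoch"),
            overlap_frac >= 0, overlap_frac < 1)
  n <- nrow(epoch$signals)
  w <- round(win_len_s * epoch$fs)
  if (w > n)
    stop(sprintf("window of %g s exceeds the %.2f s epoch", win_len_s, n / epoch$fs))
  step <- max(1L, round(w * (1 - overlap_frac)))
  n_win <- (n - w) %/% step + 1L
  lapply(seq_len(n_win), function(i) {
    a <- (i - 1L) * step + 1L
    structure(list(signals = epoch$signals[a:(a + w - 1L), , drop = FALSE],
                   fs = epoch$fs, region = epoch$region, side = epoch$side,
                   mode = epoch$mode, label = epoch$label,
                   subject_id = epoch$subject_id,
                   recording_id = epoch$recording_id,
                   task_index = epoch$task_index, window_index = i),
              class = "eeg_window")
  })
}
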