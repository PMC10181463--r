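# Synthetic multi-subject EEG generator.
#
# Emulates the acquisition protocol (8 contiguous tasks of 30 s at
# 512 Hz, 16-channel research montage or single-channel FP1 consumer
# montage, 0.5 s light-sensor pulses at task boundaries) with
# class-dependent signal statistics injected on moment-relevant
# quantities rather than on oscillatory band power, because the
# classifier consumes time-domain moments:
#
#   * mode  (real vs imagery)  -> multiplicative gain on the task's EEG
#     power (imagery tasks are generated with larger amplitude);
#   * side  (left vs right)    -> the *sign* of the signal's skewness,
#     injected by one-sided shot noise (smooth in-band pulses);
#   * region (hand vs ankle)   -> a second multiplicative gain plus
#     tail weight (excess kurtosis) injected by sparse symmetric +/-
#     shot noise of class-dependent amplitude.
#
# Shot components use a smooth Gaussian kernel whose spectrum lies
# inside the 0.5-59 Hz analysis band, so the class statistics largely
# survive band-pass preprocessing.  Background activity is 1/f
# Gaussian noise; baseline drift (random walk), 60 Hz line hum and
# frontal-only blink artifacts are added as label-independent nuisance
# structure.  Subject- and session-level log-normal random effects
# perturb the class effect parameters, creating inter-personal and
# inter-session variability.

#' Class effect sizes of the generator
#'
#' Amplitudes are in units of the background standard deviation; rates
#' in events per second.  Defaults are calibrated so that
#' within-recording (Framework 1) classification sits in the
#' high-accuracy regime.
#'
#' @param skew_amp amplitude of the one-sided (skewness-carrying) shot
#'   component; its sign follows the task's body side.
#' @param skew_rate_hz event rate of the skew component.
#' @param tail_amp named amplitudes (`hand`, `ankle`) of the symmetric
#'   heavy-tail shot component carrying the region contrast.
#' @param tail_rate_hz event rate of the tail component.
#' @param mode_gain named multiplicative gains (`real`, `imagery`) on
#'   the task's overall EEG amplitude.
#' @param region_gain named multiplicative gains (`hand`, `ankle`) on
#'   the task's overall EEG amplitude, multiplied with `mode_gain`.
#' @param skew_kernel_sd_s,tail_kernel_sd_s Gaussian shot-kernel widths
#'   (seconds) of the two components; the narrower tail kernel
#'   concentrates kurtosis per unit variance.
#' @param var_mod optional named per-class multiplicative amplitude
#'   modulation (names = class labels); default 1 for every class.
#' @return list of class `class_effects`.
#' @export
class_effects <- function(skew_amp = 2.2, skew_rate_hz = 25,
                          tail_amp = c(hand = 0.2, ankle = 1.2),
                          tail_rate_hz = 10,
                          mode_gain = c(real = 1, imagery = 2.4),
                          region_gain = c(hand = 1, ankle = 1.55),
                          skew_kernel_sd_s = 0.006,
                          tail_kernel_sd_s = 0.004,
                          var_mod = NULL) {
  if (is.null(var_mod)) {
    var_mod <- rep(1, 8)
    names(var_mod) <- protocol_classes()
  }
  stopifnot(skew_amp >= 0, all(tail_amp >= 0), all(mode_gain >= 0),
            skew_rate_hz >= 0, tail_rate_hz >= 0,
            skew_kernel_sd_s > 0, tail_kernel_sd_s > 0,
            all(region_gain >= 0),
            all(c("hand", "ankle") %in% names(tail_amp)),
            all(c("hand", "ankle") %in% names(region_gain)),
            all(c("real", "imagery") %in% names(mode_gain)))
  structure(list(skew_amp = skew_amp, skew_rate_hz = skew_rate_hz,
                 tail_amp = tail_amp, tail_rate_hz = tail_rate_hz,
                 mode_gain = mode_gain, region_gain = region_gain,
                 skew_kernel_sd_s = skew_kernel_sd_s,
                 tail_kernel_sd_s = tail_kernel_sd_s, var_mod = var_mod),
            class = "class_effects")
}

#' Scale all class effects by a common factor
#'
#' `scale_effects(e, 0)` yields a generator with no class information
#' (chance-level classification); factors between 0 and 1 shrink the
#' separability continuously.
#'
#' @param effects a [class_effects()].
#' @param factor nonnegative scale; applied to the shot amplitudes and
#'   to the imagery/real gain contrast.
#' @return rescaled `class_effects`.
#' @export
scale_effects <- function(effects, factor) {
  stopifnot(factor >= 0)
  effects$skew_amp <- effects$skew_amp * factor
  effects$tail_amp <- effects$tail_amp * factor
  effects$mode_gain["imagery"] <-
    1 + (effects$mode_gain[["imagery"]] - 1) * factor
  effects$region_gain <- 1 + (effects$region_gain - 1) * factor
  effects$var_mod <- 1 + (effects$var_mod - 1) * factor
  effects
}

#' Nuisance-noise model of the generator
#'
#' @param bg_sd background (1/f) standard deviation in microvolts.
#' @param one_over_f_exponent spectral exponent of the background.
#' @param line_hz,line_amp powerline frequency (Hz) and amplitude (uV).
#' @param drift_sd baseline-drift (random-walk) standard deviation (uV).
#' @param blink_rate_per_min blink artifact rate (frontal channels only).
#' @param blink_amp,blink_width_s blink amplitude (uV) and Gaussian
#'   width (s).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(bg_sd = 10, one_over_f_exponent = 1,
                        line_hz = 60, line_amp = 2, drift_sd = 20,
                        blink_rate_per_min = 0.5, blink_amp = 30,
                        blink_width_s = 0.15) {
  stopifnot(bg_sd >= 0, line_amp >= 0, drift_sd >= 0,
            blink_rate_per_min >= 0, blink_amp >= 0)
  structure(as.list(environment()), class = "noise_model")
}

montage_labels <- function(montage) {
  switch(montage,
         vamp16 = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "C3",
                    "C4", "Cz", "P3", "P4", "Pz", "O1", "O2", "T8"),
         fp1 = "FP1",
         stop("unknown montage: ", montage))
}

#' Simulation configuration
#'
#' @param n_subjects number of subjects (default 9).
#' @param n_recordings recordings (sessions) per subject (default 2).
#' @param montage `"vamp16"` (16-channel research montage) or `"fp1"`
#'   (single-channel consumer montage).
#' @param fs sampling rate in Hz (default 512).
#' @param protocol an [eeg_protocol()] (default: 8 tasks x 30 s).
#' @param effects a [class_effects()].
#' @param subject_sd,session_sd standard deviations of the log-normal
#'   subject- and session-level random effects perturbing the class
#'   effect parameters.
#' @param noise a [noise_model()].
#' @param trigger list: `amplitude`, `pulse_s` (0.5 s square),
#'   `boundary_mode` (`"shared"`: contiguous tasks sharing boundary
#'   pulses; `"paired"`: a `gap_s` inter-task gap with separate
#'   start/end pulses), `gap_s`.
#' @param lead_in_s,lead_out_s idle seconds before the first and after
#'   the last task.
#' @param seed master seed; all per-subject and per-recording streams
#'   derive from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 9, n_recordings = 2,
                              montage = c("vamp16", "fp1"), fs = 512,
                              protocol = default_protocol(),
                              effects = class_effects(),
                              subject_sd = 0.8, session_sd = 0.25,
                              noise = noise_model(),
                              trigger = list(amplitude = 1000, pulse_s = 0.5,
                                             boundary_mode = "shared",
                                             gap_s = 1),
                              lead_in_s = 2, lead_out_s = 2, seed = 1) {
  montage <- match.arg(montage)
  stopifnot(n_subjects >= 1, n_recordings >= 1, fs > 0,
            subject_sd >= 0, session_sd >= 0,
            trigger$amplitude >= 0, trigger$pulse_s > 0,
            lead_in_s >= 0, lead_out_s >= trigger$pulse_s)
  trigger$boundary_mode <- match.arg(trigger$boundary_mode,
                                     c("shared", "paired"))
  if (is.null(trigger$gap_s)) trigger$gap_s <- 1
  structure(list(n_subjects = n_subjects, n_recordings = n_recordings,
                 montage = montage, fs = fs, protocol = protocol,
                 effects = effects, subject_sd = subject_sd,
                 session_sd = session_sd, noise = noise, trigger = trigger,
                 lead_in_s = lead_in_s, lead_out_s = lead_out_s,
                 seed = seed),
            class = "simulation_config")
}

# deterministic sub-stream seeds (< 2^31)
stream_seed <- function(seed, subject, recording) {
  (abs(seed) %% 50000) * 40000 + subject * 200 + recording
}

# Log-normal random-effect multipliers for one subject or session.
# The dominant effect displaces each (region, mode) condition's
# amplitude gain independently (log-sd = sd), relocating the four
# gain levels without shrinking within-recording contrasts; the shot
# amplitudes and the global gain are perturbed more mildly (log-sd =
# sd/2) so that the sign-based side coding stays readable within a
# subject.
draw_effect_multipliers <- function(sd) {
  ln <- function(s) exp(stats::rnorm(1, 0, s))
  cell <- matrix(exp(stats::rnorm(4, 0, sd)), 2, 2,
                 dimnames = list(c("hand", "ankle"), c("real", "imagery")))
  list(skew = ln(sd / 2), tail_hand = ln(sd / 2), tail_ankle = ln(sd / 2),
       gain = ln(sd / 2), cell = cell)
}

gen_one_over_f <- function(n, exponent) {
  if (exponent == 0) return(stats::rnorm(n))
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)
  amp <- c(0, f[-1]^(-exponent / 2))
  z <- stats::fft(stats::rnorm(n)) * amp
  x <- Re(stats::fft(z, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

shot_kernel <- function(fs, kernel_sd_s) {
  sd_smp <- kernel_sd_s * fs
  half <- max(1L, ceiling(4 * sd_smp))
  t <- (-half):half
  exp(-t^2 / (2 * sd_smp^2))
}

# impulse train of Poisson shot events over [a, b) sample spans
impulse_train <- function(n, spans, rates_hz, amps_fun, fs) {
  imp <- numeric(n)
  for (i in seq_len(nrow(spans))) {
    span_n <- spans[i, 2] - spans[i, 1]
    k <- stats::rpois(1, rates_hz[i] * span_n / fs)
    if (k == 0) next
    pos <- spans[i, 1] + floor(stats::runif(k) * span_n) + 1L
    amp <- amps_fun(i, k)
    ag <- rowsum(amp, pos)
    idx <- as.integer(rownames(ag))
    imp[idx] <- imp[idx] + ag[, 1]
  }
  imp
}

# boundary sample indices (0-based) of every task given the config
task_spans <- function(config) {
  fs <- config$fs
  dur <- config$protocol$task_duration_s
  gap <- if (config$trigger$boundary_mode == "paired") config$trigger$gap_s else 0
  n_tasks <- nrow(config$protocol$tasks)
  starts <- config$lead_in_s + (seq_len(n_tasks) - 1) * (dur + gap)
  cbind(start = round(starts * fs), end = round((starts + dur) * fs))
}

recording_length <- function(config) {
  spans <- task_spans(config)
  spans[nrow(spans), 2] + round(config$lead_out_s * config$fs)
}

effective_params <- function(config, subject_index, recording_index) {
  set.seed(stream_seed(config$seed, subject_index, 0))
  ms <- draw_effect_multipliers(config$subject_sd)
  set.seed(stream_seed(config$seed, subject_index, recording_index))
  mr <- draw_effect_multipliers(config$session_sd)
  e <- config$effects
  list(
    skew_amp = e$skew_amp * ms$skew * mr$skew,
    tail_amp = c(hand = e$tail_amp[["hand"]] * ms$tail_hand * mr$tail_hand,
                 ankle = e$tail_amp[["ankle"]] * ms$tail_ankle * mr$tail_ankle),
    mode_gain = e$mode_gain,
    region_gain = e$region_gain,
    cell_gain = ms$cell * mr$cell,
    gain = ms$gain * mr$gain
  )
}

#' Simulate one recording
#'
#' Deterministic given `(config$seed, subject_index, recording_index)`:
#' the subject's random effects are drawn from a subject-specific
#' stream (shared across that subject's recordings) and everything
#' else from a recording-specific stream.
#'
#' @param config a [simulation_config()].
#' @param subject_index,recording_index 1-based indices.
#' @return an [eeg_recording()] with a trigger channel carrying 0.5 s
#'   pulses at the task boundaries.
#' @export
simulate_recording <- function(config, subject_index = 1,
                               recording_index = 1) {
  stopifnot(inherits(config, "simulation_config"),
            subject_index >= 1, subject_index <= config$n_subjects,
            recording_index >= 1, recording_index <= config$n_recordings)
  fs <- config$fs
  par <- effective_params(config, subject_index, recording_index)
  # the stream is positioned just after the session-effect draws
  labels <- montage_labels(config$montage)
  n_ch <- length(labels)
  spans <- task_spans(config)
  n <- recording_length(config)
  tasks <- config$protocol$tasks
  nz <- config$noise
  ef <- config$effects
  kern_p <- shot_kernel(fs, ef$skew_kernel_sd_s)
  kern_q <- shot_kernel(fs, ef$tail_kernel_sd_s)

  # per-task shot parameters
  skew_sign <- ifelse(tasks$side == "right", 1, -1)
  a_skew <- par$skew_amp * skew_sign
  b_tail <- par$tail_amp[tasks$region]
  g_task <- par$mode_gain[tasks$mode] * par$region_gain[tasks$region] *
    par$cell_gain[cbind(tasks$region, tasks$mode)] * ef$var_mod[tasks$label]

  frontal <- grepl("^fp", tolower(labels))
  n_blinks <- stats::rpois(1, nz$blink_rate_per_min * n / fs / 60)
  blink_pos <- floor(stats::runif(n_blinks) * n) + 1L
  blink <- numeric(n)
  if (n_blinks > 0 && nz$blink_amp > 0) {
    half <- ceiling(4 * nz$blink_width_s * fs)
    tt <- (-half):half
    bk <- nz$blink_amp * exp(-tt^2 / (2 * (nz$blink_width_s * fs)^2))
    for (p in blink_pos) {
      idx <- (p + tt)
      ok <- idx >= 1 & idx <= n
      blink[idx[ok]] <- blink[idx[ok]] + bk[ok]
    }
  }

  sig <- matrix(0, nrow = n, ncol = n_ch)
  for (j in seq_len(n_ch)) {
    core <- if (nz$bg_sd > 0) gen_one_over_f(n, nz$one_over_f_exponent) else numeric(n)
    if (ef$skew_amp > 0 && ef$skew_rate_hz > 0) {
      imp <- impulse_train(n, spans, rep(ef$skew_rate_hz, nrow(spans)),
                           function(i, k) rep(a_skew[i], k), fs)
      sh <- stats::filter(imp, kern_p, sides = 2)
      core <- core + ifelse(is.na(sh), 0, sh)
    }
    if (any(ef$tail_amp > 0) && ef$tail_rate_hz > 0) {
      imp <- impulse_train(n, spans, rep(ef$tail_rate_hz, nrow(spans)),
                           function(i, k) b_tail[i] * sample(c(-1, 1), k, replace = TRUE),
                           fs)
      sh <- stats::filter(imp, kern_q, sides = 2)
      core <- core + ifelse(is.na(sh), 0, sh)
    }
    # per-task amplitude gain (mode and per-class modulation)
    gain_vec <- rep(1, n)
    for (i in seq_len(nrow(spans)))
      gain_vec[(spans[i, 1] + 1L):spans[i, 2]] <- g_task[i]
    x <- nz$bg_sd * par$gain * core * gain_vec
    if (nz$drift_sd > 0) {
      rw <- cumsum(stats::rnorm(n))
      x <- x + nz$drift_sd * (rw - mean(rw)) / max(stats::sd(rw), 1e-12)
    }
    if (nz$line_amp > 0)
      x <- x + nz$line_amp * sin(2 * pi * nz$line_hz * (seq_len(n) - 1) / fs +
                                   stats::runif(1, 0, 2 * pi))
    if (frontal[j]) x <- x + blink
    sig[, j] <- x
  }

  trig <- numeric(n)
  pw <- round(config$trigger$pulse_s * fs)
  onsets <- if (config$trigger$boundary_mode == "shared") {
    c(spans[, 1], spans[nrow(spans), 2])
  } else {
    as.vector(rbind(spans[, 1], spans[, 2] - pw))
  }
  for (o in onsets) {
    idx <- (o + 1L):min(o + pw, n)
    trig[idx] <- config$trigger$amplitude
  }

  eeg_recording(sig, fs = fs, channel_labels = labels, trigger = trig,
                subject_id = sprintf("S%02d", subject_index),
                recording_id = sprintf("R%d", recording_index))
}

#' Expected class statistics implied by the generative model
#'
#' Closed-form moments of the stationary class-dependent part of the
#' signal (1/f background + shot components, including the task gain),
#' via Campbell's theorem for discrete-time shot noise.  Nuisance
#' structure (drift, line hum, blinks) is excluded; statistics refer to
#' the raw (unfiltered) generator output.  Identical for every channel.
#'
#' @param config a [simulation_config()].
#' @param subject_index,recording_index indices selecting the random
#'   effects.
#' @param class_label one of the eight activity labels.
#' @return list with `variance` (uV^2), `skewness` and `ex_kurtosis`.
#' @export
class_statistics_oracle <- function(config, subject_index, recording_index,
                                    class_label) {
  cls <- config$protocol$tasks
  i <- match(class_label, cls$label)
  if (is.na(i)) stop("unknown class: ", class_label)
  par <- effective_params(config, subject_index, recording_index)
  ef <- config$effects
  fs <- config$fs
  kp <- shot_kernel(fs, ef$skew_kernel_sd_s)
  kq <- shot_kernel(fs, ef$tail_kernel_sd_s)
  p2 <- sum(kp^2); p3 <- sum(kp^3); p4 <- sum(kp^4)
  q2 <- sum(kq^2); q4 <- sum(kq^4)
  lp <- ef$skew_rate_hz / fs
  lq <- ef$tail_rate_hz / fs
  a <- par$skew_amp
  b <- par$tail_amp[[cls$region[i]]]
  sgn <- if (cls$side[i] == "right") 1 else -1
  k2 <- 1 + lp * a^2 * p2 + lq * b^2 * q2
  k3 <- sgn * lp * a^3 * p3
  k4 <- lp * a^4 * p4 + lq * b^4 * q4
  g <- config$noise$bg_sd * par$gain * par$mode_gain[[cls$mode[i]]] *
    par$region_gain[[cls$region[i]]] *
    par$cell_gain[cls$region[i], cls$mode[i]] * ef$var_mod[[cls$label[i]]]
  list(variance = g^2 * k2,
       skewness = k3 / k2^1.5,
       ex_kurtosis = k4 / k2^2)
}

#' Generate a dataset of recordings on disk
#'
#' Writes `n_subjects x n_recordings` recordings in the chosen dialect
#' plus a `manifest.json` listing files, stream seeds and the true
#' class statistics of each recording.  Regenerating with the same
#' config reproduces the files byte-identically.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @param dialect `"csv"` or `"edf"`.
#' @return path of the manifest, invisibly.
#' @export
generate_dataset <- function(config, dir, dialect = c("csv", "edf")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (s in seq_len(config$n_subjects)) {
    for (r in seq_len(config$n_recordings)) {
      rec <- simulate_recording(config, s, r)
      fn <- sprintf("sub%02d_rec%d.%s", s, r, dialect)
      write_recording(rec, file.path(dir, fn), dialect)
      stats <- lapply(protocol_classes(config$protocol), function(cl)
        class_statistics_oracle(config, s, r, cl))
      names(stats) <- protocol_classes(config$protocol)
      files[[fn]] <- list(file = fn, subject_id = rec$subject_id,
                          recording_id = rec$recording_id,
                          subject_index = s, recording_index = r,
                          stream_seed = stream_seed(config$seed, s, r),
                          class_statistics = stats)
    }
  }
  manifest <- list(seed = config$seed, montage = config$montage,
                   fs = config$fs, dialect = dialect,
                   n_subjects = config$n_subjects,
                   n_recordings = config$n_recordings,
                   files = unname(files))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mp)
}
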