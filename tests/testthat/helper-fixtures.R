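# Fixtures built in code: tiny recordings, triggers and feature tables.

# rectangular trigger with pulses at the given onset seconds
make_trigger <- function(duration_s, onsets_s, fs = 512, pulse_s = 0.5,
                         amplitude = 100) {
  n <- round(duration_s * fs)
  trig <- numeric(n)
  for (o in onsets_s) {
    idx <- (round(o * fs) + 1):(round(o * fs) + round(pulse_s * fs))
    trig[idx[idx <= n]] <- amplitude
  }
  trig
}

# two-channel deterministic recording for i/o round trips
make_tiny_recording <- function(seconds = 1, fs = 512) {
  n <- seconds * fs
  t <- (0:(n - 1)) / fs
  sig <- cbind(A1 = 50 * sin(2 * pi * 5 * t), A2 = 20 * cos(2 * pi * 11 * t))
  eeg_recording(sig, fs = fs, trigger = make_trigger(seconds, 0.1, fs, 0.2),
                subject_id = "S09", recording_id = "R2")
}

# feature table with separable structure along the three dichotomies:
# C3_m2 codes region, C4_m3 codes side, Cz_m4 codes mode; extra pure
# noise features can be appended.
make_toy_table <- function(n_per_class = 12, sep = 4, noise_feats = 0,
                           noise_sd = 0.5, seed = 1, subject_id = "S01",
                           recording_id = "R1", classes = protocol_classes()) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_along(classes), function(i) {
    parts <- strsplit(classes[i], "-")[[1]]
    data.frame(mode = parts[1], side = parts[2], region = parts[3],
               label = classes[i], task_index = i,
               window_index = seq_len(n_per_class))
  }))
  n <- nrow(rows)
  tab <- data.frame(subject_id = subject_id, recording_id = recording_id,
                    task_index = rows$task_index,
                    window_index = rows$window_index,
                    region = rows$region, side = rows$side,
                    mode = rows$mode, label = rows$label,
                    stringsAsFactors = FALSE)
  tab$C3_m2 <- ifelse(rows$region == "ankle", sep, 0) + rnorm(n, 0, noise_sd)
  tab$C4_m3 <- ifelse(rows$side == "right", sep, 0) + rnorm(n, 0, noise_sd)
  tab$Cz_m4 <- ifelse(rows$mode == "imagery", sep, 0) + rnorm(n, 0, noise_sd)
  if (noise_feats > 0)
    for (k in seq_len(noise_feats))
      tab[[sprintf("P%d_m%d", k, 4 + (k %% 6) + 1)]] <- rnorm(n)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

# pure-noise table (no class information at all)
make_noise_table <- function(n_per_class, n_feats = 10, seed = 1, ...) {
  tab <- make_toy_table(n_per_class, sep = 0, noise_feats = 0, seed = seed, ...)
  tab$C3_m2 <- NULL; tab$C4_m3 <- NULL; tab$Cz_m4 <- NULL
  set.seed(seed + 1)
  for (k in seq_len(n_feats))
    tab[[sprintf("F%d_m%d", k, (k %% 10) + 1)]] <- rnorm(nrow(tab))
  class(tab) <- c("feature_table", "data.frame")
  tab
}

# quick simulated single-recording feature table
sim_table <- function(seed, montage = "fp1", subject_sd = 0, session_sd = 0,
                      effects = class_effects(), subject = 1, recording = 1,
                      n_subjects = max(1, subject),
                      n_recordings = max(1, recording), ...) {
  cfg <- simulation_config(montage = montage, n_subjects = n_subjects,
                           n_recordings = n_recordings,
                           subject_sd = subject_sd, session_sd = session_sd,
                           effects = effects, seed = seed)
  extract_features(simulate_recording(cfg, subject, recording), ...)
}
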