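test_that("a default recording covers the full protocol with 9 shared pulses", {
  cfg <- simulation_config(montage = "fp1", seed = 2)
  rec <- simulate_recording(cfg, 1, 1)
  expect_gte(nrow(rec$signals) / rec$fs, 240)
  p <- detect_trigger_pulses(rec$trigger, rec$fs)
  expect_equal(nrow(p), 9)
  expect_equal(unique(p$offset - p$onset), 256)
})

test_that("simulation is bit-identical under a fixed (seed, subject, recording)", {
  cfg <- simulation_config(montage = "fp1", seed = 17)
  r1 <- simulate_recording(cfg, 3, 2)
  r2 <- simulate_recording(cfg, 3, 2)
  expect_identical(r1$signals, r2$signals)
  expect_identical(r1$trigger, r2$trigger)
  r3 <- simulate_recording(cfg, 3, 1)
  expect_false(identical(r1$signals, r3$signals))
})

test_that("zeroed noise and effects produce silence plus the trigger", {
  cfg <- simulation_config(montage = "fp1", subject_sd = 0, session_sd = 0,
                           seed = 1,
                           effects = scale_effects(class_effects(), 0),
                           noise = noise_model(bg_sd = 0, line_amp = 0,
                                               drift_sd = 0,
                                               blink_rate_per_min = 0,
                                               blink_amp = 0))
  rec <- simulate_recording(cfg, 1, 1)
  expect_equal(max(abs(rec$signals)), 0)
  expect_equal(max(rec$trigger), 1000)
})

test_that("the class-statistics oracle matches the generative construction", {
  base <- simulation_config(montage = "fp1", subject_sd = 0, session_sd = 0,
                            seed = 1)
  # zero effects: identical statistics across classes
  cfg0 <- simulation_config(montage = "fp1", subject_sd = 0, session_sd = 0,
                            seed = 1,
                            effects = scale_effects(class_effects(), 0))
  stats0 <- lapply(protocol_classes(), function(cl)
    class_statistics_oracle(cfg0, 1, 1, cl))
  expect_length(unique(vapply(stats0, `[[`, 0, "variance")), 1)
  expect_true(all(vapply(stats0, `[[`, 0, "skewness") == 0))
  # per-class amplitude modulation sqrt(2) doubles the expected variance
  vm <- rep(1, 8); names(vm) <- protocol_classes()
  vm["real-left-hand"] <- sqrt(2)
  cfgv <- simulation_config(montage = "fp1", subject_sd = 0, session_sd = 0,
                            seed = 1, effects = class_effects(var_mod = vm))
  o1 <- class_statistics_oracle(cfgv, 1, 1, "real-left-hand")
  o2 <- class_statistics_oracle(cfgv, 1, 1, "real-right-hand")
  expect_equal(o1$variance / o2$variance, 2, tolerance = 1e-12)
  expect_equal(o1$skewness, -o2$skewness)
  expect_error(class_statistics_oracle(base, 1, 1, "jumping"), "unknown")
})

test_that("estimated window variance converges to the oracle value", {
  # white background: 2 s windows then capture the process variance
  # without the low-frequency leakage a 1/f background would add
  cfg <- simulation_config(montage = "fp1", subject_sd = 0.5, session_sd = 0.2,
                           seed = 41,
                           noise = noise_model(one_over_f_exponent = 0,
                                               line_amp = 0, drift_sd = 0,
                                               blink_rate_per_min = 0))
  pro <- default_protocol()
  # average m2 over the 2 s windows of several independent recordings
  est <- list(); want <- list()
  for (r in 1:2) {
    rec <- simulate_recording(cfg, 2, r)
    p <- detect_trigger_pulses(rec$trigger, rec$fs)
    eps <- segment_tasks(rec, p, pro)
    for (ep in eps) {
      w <- window_epoch(ep, 2, 0)
      m2 <- vapply(w, function(x)
        statistical_moments(x$signals[, 1], moment_spec(2))[[1]], 0)
      o <- class_statistics_oracle(cfg, 2, r, ep$label)
      est[[paste(r, ep$label)]] <- mean(m2)
      want[[paste(r, ep$label)]] <- o$variance
    }
  }
  rel <- abs(unlist(est) - unlist(want)) / unlist(want)
  expect_lt(mean(rel), 0.10)
  # signed statistics follow the construction: right-side tasks skew
  # positive, left-side negative
  rec <- simulate_recording(cfg, 2, 1)
  eps <- segment_tasks(rec, detect_trigger_pulses(rec$trigger, rec$fs), pro)
  sk <- vapply(eps, function(ep) {
    x <- ep$signals[, 1]
    mean((x - mean(x))^3) / stats::var(x)^1.5
  }, 0)
  expect_true(all(sk[vapply(eps, `[[`, "", "side") == "right"] > 0))
  expect_true(all(sk[vapply(eps, `[[`, "", "side") == "left"] < 0))
})

test_that("blink artifacts land only on frontal channels", {
  cfg <- simulation_config(montage = "vamp16", subject_sd = 0, session_sd = 0,
                           seed = 13,
                           effects = scale_effects(class_effects(), 0),
                           noise = noise_model(bg_sd = 2, line_amp = 0,
                                               drift_sd = 0,
                                               blink_rate_per_min = 10,
                                               blink_amp = 80))
  rec <- simulate_recording(cfg, 1, 1)
  peak <- apply(abs(rec$signals), 2, max)
  frontal <- grepl("^fp", tolower(rec$channel_labels))
  expect_true(min(peak[frontal]) > 3 * max(peak[!frontal]))
})

test_that("line noise concentrates at 60 Hz and is attenuated by the band-pass", {
  cfg <- simulation_config(montage = "fp1", subject_sd = 0, session_sd = 0,
                           seed = 19,
                           effects = scale_effects(class_effects(), 0),
                           noise = noise_model(bg_sd = 1, line_amp = 20,
                                               drift_sd = 0,
                                               blink_rate_per_min = 0))
  rec <- simulate_recording(cfg, 1, 1)
  x <- rec$signals[1025:(1024 + 60 * 512), 1]
  band_power <- function(sig, lo, hi) {
    sp <- Mod(stats::fft(sig))^2
    f <- (seq_along(sig) - 1) * 512 / length(sig)
    sum(sp[f >= lo & f <= hi])
  }
  expect_gt(band_power(x, 59.5, 60.5) / band_power(x, 10, 11), 10)
  # the preprocessing filter attenuates 60 Hz per its own response
  y <- bandpass_filter(x, 512)
  got <- sqrt(band_power(y, 59.5, 60.5) / band_power(x, 59.5, 60.5))
  expect_equal(got, filter_response(filter_spec(), 512, 60), tolerance = 0.05)
})

test_that("generate_dataset writes all recordings plus a reproducible manifest", {
  cfg <- simulation_config(n_subjects = 2, n_recordings = 2, montage = "fp1",
                           seed = 23)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(cfg, d1, "csv")
  files <- list.files(d1)
  expect_length(grep("\\.csv$", files), 4)
  man <- jsonlite::read_json(file.path(d1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_subjects, 2)
  rec <- read_recording(file.path(d1, man$files$file[1]), "csv")
  expect_identical(rec$channel_labels, "FP1")
  # regeneration is byte-identical
  generate_dataset(cfg, d2, "csv")
  for (f in grep("csv$", files, value = TRUE))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})
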