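# End-to-end drivers: recording -> features -> framework -> report.

#' Extract the feature table of one recording
#'
#' Runs the standard preprocessing chain: band-pass filter the
#' continuous recording (filtering before segmentation avoids edge
#' transients inside epochs), optionally z-score each channel over the
#' whole recording, detect trigger pulses, segment into task epochs,
#' trim the epoch edges, cut windows and compute moment features.
#'
#' @param recording an [eeg_recording()].
#' @param protocol an [eeg_protocol()].
#' @param fspec a [filter_spec()].
#' @param mspec a [moment_spec()].
#' @param trim_s seconds trimmed at each epoch edge (default 5).
#' @param win_len_s,overlap_frac windowing parameters (default 2 s,
#'   overlap 0.5, i.e. 19 windows per 20 s task).
#' @param boundary_mode trigger pulse convention, see [segment_tasks()].
#' @param threshold,min_width_s trigger detection parameters.
#' @return a feature table.
#' @export
extract_features <- function(recording, protocol = default_protocol(),
                             fspec = filter_spec(), mspec = moment_spec(),
                             trim_s = 5, win_len_s = 2, overlap_frac = 0.5,
                             boundary_mode = "shared",
                             threshold = 0.5, min_width_s = 0.25) {
  filt <- bandpass_filter(recording$signals, recording$fs, fspec)
  if (mspec$normalize == "recording") {
    for (j in seq_len(ncol(filt))) {
      s <- stats::sd(filt[, j])
      filt[, j] <- (filt[, j] - mean(filt[, j])) / max(s, .Machine$double.eps)
    }
  }
  rec_f <- recording
  rec_f$signals <- filt
  colnames(rec_f$signals) <- recording$channel_labels
  pulses <- detect_trigger_pulses(recording$trigger, recording$fs,
                                  threshold, min_width_s)
  epochs <- segment_tasks(rec_f, pulses, protocol, boundary_mode)
  windows <- unlist(lapply(epochs, function(ep)
    window_epoch(trim_epoch(ep, trim_s), win_len_s, overlap_frac)),
    recursive = FALSE)
  build_feature_table(windows, mspec)
}

#' Feature tables for a generated dataset directory
#'
#' Reads every recording listed in a [generate_dataset()] manifest and
#' extracts its features.
#'
#' @param dir dataset directory containing `manifest.json`.
#' @param ... passed to [extract_features()].
#' @return nested list: `tables[[subject_id]][[recording_id]]`.
#' @export
dataset_features <- function(dir, ...) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  tables <- list()
  for (f in manifest$files) {
    rec <- read_recording(file.path(dir, f$file), manifest$dialect)
    tables[[f$subject_id]][[f$recording_id]] <- extract_features(rec, ...)
  }
  tables
}

#' Run Framework 1 on one subject-recording table
#'
#' @param table feature table of a single (subject, recording).
#' @param seed integer seed (split and training).
#' @param selection,grid passed to [train_cascade()].
#' @return an `evaluation_report`; the trained model is attached as
#'   `meta$model`.
#' @export
run_framework1 <- function(table, seed = 1L,
                           selection = list(learner = learner_config(50),
                                            max_k = 10, tol = 0.001),
                           grid = default_grid()) {
  plan <- split_framework1(table, seed)
  model <- train_cascade(split_train(plan), split_val(plan),
                         selection, grid, seed)
  test <- split_test(plan)
  cm <- confusion_matrix(test$label, predict_cascade(model, test))
  rep <- evaluation_report(cm, 1L,
                           meta = list(subject_id = unique(table$subject_id),
                                       recording_id = unique(table$recording_id),
                                       seed = seed))
  rep$meta$model <- model
  rep
}

#' Run Framework 2 on two recordings of one subject
#'
#' @param rec1,rec2 feature tables (train/validate on `rec1`, test on
#'   `rec2`).
#' @inheritParams run_framework1
#' @return an `evaluation_report`.
#' @export
run_framework2 <- function(rec1, rec2, seed = 1L,
                           selection = list(learner = learner_config(50),
                                            max_k = 10, tol = 0.001),
                           grid = default_grid()) {
  plan <- split_framework2(rec1, rec2, seed)
  model <- train_cascade(split_train(plan), split_val(plan),
                         selection, grid, seed)
  test <- split_test(plan)
  cm <- confusion_matrix(test$label, predict_cascade(model, test))
  rep <- evaluation_report(cm, 2L,
                           meta = list(subject_id = unique(rec1$subject_id),
                                       train_recording = unique(rec1$recording_id),
                                       test_recording = unique(rec2$recording_id),
                                       seed = seed))
  rep$meta$model <- model
  rep
}

#' Run Framework 3 across subjects
#'
#' Trains on the pooled best and worst subjects (as determined by
#' Framework 1, or as given) and tests on every remaining subject,
#' reporting per-subject confusion matrices, their average (each
#' row-normalized) and the mean macro accuracy.
#'
#' @param subject_tables named list of per-subject feature tables.
#' @param best_id,worst_id training subjects; if `NULL`, Framework 1 is
#'   run on each subject's first recording to determine them.
#' @inheritParams run_framework1
#' @return list of class `framework3_result`: `reports` (per test
#'   subject), `average_confusion`, `mean_macro`, `best_id`, `worst_id`.
#' @export
run_framework3 <- function(subject_tables, best_id = NULL, worst_id = NULL,
                           seed = 1L,
                           selection = list(learner = learner_config(50),
                                            max_k = 10, tol = 0.001),
                           grid = default_grid()) {
  if (is.null(best_id) || is.null(worst_id)) {
    acc <- vapply(subject_tables, function(tb) {
      first <- tb[tb$recording_id == tb$recording_id[1], , drop = FALSE]
      run_framework1(first, seed, selection, grid)$macro_accuracy
    }, 0)
    bw <- best_worst_subjects(acc)
    best_id <- bw$best_id; worst_id <- bw$worst_id
  }
  plan <- split_framework3(subject_tables, best_id, worst_id, seed)
  model <- train_cascade(split_train(plan), split_val(plan),
                         selection, grid, seed)
  test <- split_test(plan)
  test_ids <- sort(unique(test$subject_id), method = "radix")
  reports <- lapply(test_ids, function(sid) {
    tt <- test[test$subject_id == sid, , drop = FALSE]
    cm <- confusion_matrix(tt$label, predict_cascade(model, tt))
    evaluation_report(cm, 3L, meta = list(subject_id = sid, seed = seed,
                                          best_id = best_id,
                                          worst_id = worst_id))
  })
  names(reports) <- test_ids
  structure(list(reports = reports,
                 average_confusion = average_confusion(
                   lapply(reports, `[[`, "confusion")),
                 mean_macro = mean(vapply(reports, `[[`, 0, "macro_accuracy")),
                 best_id = best_id, worst_id = worst_id,
                 model = model, seed = seed),
            class = "framework3_result")
}

#' @export
print.framework3_result <- function(x, ...) {
  cat(sprintf("<framework3_result> train: %s + %s; %d test subjects; mean macro accuracy %.3f\n",
              x$best_id, x$worst_id, length(x$reports), x$mean_macro))
  invisible(x)
}
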