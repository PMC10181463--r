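# Evaluation frameworks and metrics.
#
# Framework 1 splits one recording of one subject 60/20/20 into
# train/validation/test (within-recording generalization).  Framework 2
# trains and validates on one recording and tests on the other
# recording of the same subject (cross-session), giving overall
# fractions 40/10/50 for equal-sized recordings.  Framework 3 trains
# and validates on the pooled data of the best and worst Framework-1
# subjects and tests on every remaining subject (cross-subject),
# approximately 18/4/78 for nine equal-sized subjects.

stratified_assign <- function(labels, fractions, seed) {
  set.seed(seed)
  parts <- vector("list", length(fractions) + 1L)
  n_all <- length(labels)
  assignment <- integer(n_all)
  for (cl in sort(unique(labels), method = "radix")) {
    idx <- which(labels == cl)
    n <- length(idx)
    if (n < length(fractions) + 1L)
      stop(sprintf("class '%s' has only %d rows; cannot split into %d subsets",
                   cl, n, length(fractions) + 1L))
    idx <- sample(idx)
    counts <- round(fractions * n)
    counts <- c(counts, n - sum(counts))
    if (counts[length(counts)] < 1)  # guarantee a nonempty last subset
      counts[c(1L, length(counts))] <- counts[c(1L, length(counts))] + c(-1L, 1L)
    grp <- rep(seq_along(counts), counts)
    assignment[idx] <- grp
  }
  assignment
}

new_split_plan <- function(framework, table, train_idx, val_idx, test_idx,
                           seed, fractions) {
  structure(list(framework = framework, table = table,
                 train_idx = train_idx, val_idx = val_idx,
                 test_idx = test_idx, seed = seed, fractions = fractions),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  n <- nrow(x$table)
  cat(sprintf("<split_plan> Framework %d: %d train / %d val / %d test of %d rows (%.0f%%/%.0f%%/%.0f%%)\n",
              x$framework, length(x$train_idx), length(x$val_idx),
              length(x$test_idx), n,
              100 * length(x$train_idx) / n, 100 * length(x$val_idx) / n,
              100 * length(x$test_idx) / n))
  invisible(x)
}

#' Rows of a split plan's subsets
#' @param plan a split plan.
#' @return feature table subset.
#' @export
split_train <- function(plan) plan$table[plan$train_idx, , drop = FALSE]

#' @rdname split_train
#' @export
split_val <- function(plan) plan$table[plan$val_idx, , drop = FALSE]

#' @rdname split_train
#' @export
split_test <- function(plan) plan$table[plan$test_idx, , drop = FALSE]

#' Framework 1: within-recording split
#'
#' Stratified 60/20/20 train/validation/test split of a single
#' subject-recording feature table; per-class subset counts are within
#' one row of the exact fractions.
#'
#' @param table feature table of one (subject, recording).
#' @param seed integer seed.
#' @param fractions train and validation fractions (test takes the
#'   remainder).
#' @return a `split_plan`.
#' @export
split_framework1 <- function(table, seed = 1L, fractions = c(0.6, 0.2)) {
  if (length(unique(table$subject_id)) != 1 ||
      length(unique(table$recording_id)) != 1)
    stop("Framework 1 expects a single (subject, recording) table")
  g <- stratified_assign(table$label, fractions, seed)
  new_split_plan(1L, table, which(g == 1L), which(g == 2L), which(g == 3L),
                 seed, c(fractions, 1 - sum(fractions)))
}

#' Framework 2: cross-session split
#'
#' Trains and validates on one recording (stratified 80/20) and tests
#' on the other recording of the same subject; with equal-sized
#' recordings the overall fractions are 40/10/50.
#'
#' @param rec1,rec2 feature tables of two recordings of one subject.
#' @param seed integer seed.
#' @param train_frac fraction of `rec1` used for training (default 0.8).
#' @return a `split_plan` over the concatenation of both tables.
#' @export
split_framework2 <- function(rec1, rec2, seed = 1L, train_frac = 0.8) {
  s1 <- unique(rec1$subject_id); s2 <- unique(rec2$subject_id)
  if (length(s1) != 1 || length(s2) != 1 || !identical(s1, s2))
    stop("Framework 2 requires two recordings of the same subject")
  r1 <- unique(rec1$recording_id); r2 <- unique(rec2$recording_id)
  if (length(r1) != 1 || length(r2) != 1 || identical(r1, r2))
    stop("Framework 2 requires two distinct recordings")
  table <- rbind(rec1, rec2)
  class(table) <- class(rec1)
  g <- stratified_assign(rec1$label, train_frac, seed)
  new_split_plan(2L, table, which(g == 1L), which(g == 2L),
                 nrow(rec1) + seq_len(nrow(rec2)), seed,
                 fractions = c(train_frac, 1 - train_frac, NA))
}

#' Framework 3: cross-subject split
#'
#' Trains and validates (stratified 82/18) on the pooled rows of the
#' best and worst Framework-1 subjects and tests on all rows of every
#' remaining subject; with nine equal-sized subjects the overall
#' fractions are about 18/4/78.
#'
#' @param subject_tables named list of feature tables, one per subject
#'   (each may pool several recordings).
#' @param best_id,worst_id the two training subjects.
#' @param seed integer seed.
#' @param train_frac fraction of the pooled rows used for training
#'   (default 0.82).
#' @return a `split_plan` over the concatenation of all subjects.
#' @export
split_framework3 <- function(subject_tables, best_id, worst_id, seed = 1L,
                             train_frac = 0.82) {
  if (length(subject_tables) < 3)
    stop("Framework 3 needs at least 3 subjects")
  if (identical(best_id, worst_id)) stop("best_id and worst_id must differ")
  ids <- names(subject_tables)
  if (!all(c(best_id, worst_id) %in% ids))
    stop("unknown subject id among best_id/worst_id")
  ord <- c(best_id, worst_id, setdiff(ids, c(best_id, worst_id)))
  tabs <- subject_tables[ord]
  table <- do.call(rbind, tabs)
  class(table) <- class(tabs[[1]])
  n_pool <- nrow(tabs[[1]]) + nrow(tabs[[2]])
  pool_labels <- table$label[seq_len(n_pool)]
  g <- stratified_assign(pool_labels, train_frac, seed)
  new_split_plan(3L, table, which(g == 1L), which(g == 2L),
                 n_pool + seq_len(nrow(table) - n_pool), seed,
                 fractions = c(train_frac, 1 - train_frac, NA))
}

#' Confusion matrix over the eight activity classes
#'
#' @param truths,preds equal-length label vectors.
#' @param classes class alphabet fixing the row/column order (default:
#'   protocol order).
#' @return integer matrix; entry (i, j) counts rows of true class i
#'   predicted as class j.
#' @export
confusion_matrix <- function(truths, preds, classes = protocol_classes()) {
  if (length(truths) != length(preds))
    stop("truths and preds must have equal length")
  bad <- setdiff(unique(c(truths, preds)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  t_f <- factor(truths, levels = classes)
  p_f <- factor(preds, levels = classes)
  m <- table(t_f, p_f)
  out <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(true = classes, predicted = classes))
  out
}

#' Macro-averaged per-activity accuracy
#'
#' Mean over classes of the confusion matrix's row-normalized diagonal
#' (each activity's accuracy), the study's summary metric.
#'
#' @param matrix confusion matrix with one row per true class.
#' @return numeric scalar in `[0, 1]`.
#' @export
macro_activity_accuracy <- function(matrix) {
  rs <- rowSums(matrix)
  if (any(rs == 0))
    stop("confusion matrix has an empty class (all-zero row)")
  mean(diag(matrix) / rs)
}

#' Average several confusion matrices
#'
#' Each matrix is row-normalized (per-class rates), then the entrywise
#' mean is taken; rows of the result sum to 1.
#'
#' @param matrices nonempty list of confusion matrices of equal shape.
#' @return numeric matrix of averaged per-class rates.
#' @export
average_confusion <- function(matrices) {
  if (length(matrices) == 0) stop("need at least one confusion matrix")
  norm <- lapply(matrices, function(m) {
    rs <- rowSums(m)
    if (any(rs == 0)) stop("confusion matrix has an all-zero row")
    m / rs
  })
  Reduce(`+`, norm) / length(norm)
}

#' Best and worst subjects by macro activity accuracy
#'
#' @param reports named list of evaluation reports (or a named numeric
#'   vector of macro accuracies), one entry per subject.
#' @return list with `best_id` and `worst_id`; ties are broken by
#'   subject id order.
#' @export
best_worst_subjects <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 subjects")
  acc <- if (is.numeric(reports)) reports
         else vapply(reports, function(r) r$macro_accuracy, 0)
  ids <- names(acc)
  ord <- order(ids, method = "radix")
  acc <- acc[ord]; ids <- ids[ord]
  list(best_id = ids[which.max(acc)], worst_id = ids[which.min(acc)])
}

#' Bundle a confusion matrix into an evaluation report
#'
#' @param confusion 8x8 confusion matrix.
#' @param framework framework number.
#' @param meta named list of metadata (subject ids, seeds, ...).
#' @return list of class `evaluation_report` with the matrix,
#'   per-activity accuracies and their macro average.
#' @export
evaluation_report <- function(confusion, framework, meta = list()) {
  structure(list(confusion = confusion,
                 per_activity = diag(confusion) / rowSums(confusion),
                 macro_accuracy = macro_activity_accuracy(confusion),
                 framework = framework, meta = meta),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> Framework %s: macro activity accuracy %.3f\n",
              x$framework, x$macro_accuracy))
  print(round(x$per_activity, 3))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes `<stem>.json` (metadata, per-activity accuracies, macro
#' average) and `<stem>_confusion.csv` (the matrix).
#'
#' @param report an `evaluation_report`.
#' @param stem path stem without extension.
#' @return `stem`, invisibly.
#' @export
write_report <- function(report, stem) {
  jsonlite::write_json(
    list(framework = report$framework,
         macro_accuracy = report$macro_accuracy,
         per_activity = as.list(report$per_activity),
         meta = report$meta),
    paste0(stem, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(report$confusion, paste0(stem, "_confusion.csv"))
  invisible(stem)
}
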