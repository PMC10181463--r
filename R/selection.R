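#' Greedy forward feature selection
#'
#' Starting from an empty set, repeatedly adds the feature whose
#' addition maximizes validation accuracy of a forest retrained on the
#' enlarged set; stops when the best improvement falls below `tol` or
#' `max_k` features have been selected.  Ties between candidates are
#' broken by column order.  Deterministic under a fixed seed (every
#' candidate fit uses the same seed, so re-evaluating the returned set
#' reproduces the reported accuracy exactly).
#'
#' @param train,val feature tables sharing the same feature columns.
#' @param target name of the label column to predict (e.g. `"region"`,
#'   `"side"`, `"mode"` or `"label"`).
#' @param learner a [learner_config()] used for every candidate fit.
#' @param max_k maximum number of features to select (default 10;
#'   clamped to the number of available features with a warning).
#' @param tol minimum accuracy improvement to keep adding (default 0.001).
#' @param seed integer seed.
#' @return list of class `selection_result` with elements `selected`
#'   (ordered feature names), `accuracy_curve` (validation accuracy
#'   after each addition) and `stopped_because` (`"tol"`, `"max_k"` or
#'   `"exhausted"`).
#' @export
greedy_forward_selection <- function(train, val, target = "label",
                                     learner = learner_config(),
                                     max_k = 10, tol = 0.001, seed = 1L) {
  feats <- feature_columns(train)
  stopifnot(length(feats) > 0, identical(feats, feature_columns(val)))
  if (max_k < 1) stop("max_k must be at least 1")
  if (max_k > length(feats)) {
    warning(sprintf("max_k = %d exceeds the %d available features; clamped",
                    max_k, length(feats)))
    max_k <- length(feats)
  }
  y_tr <- train[[target]]
  y_va <- val[[target]]
  selected <- character(0)
  curve <- numeric(0)
  best_acc <- -Inf
  stopped <- "exhausted"
  repeat {
    remaining <- setdiff(feats, selected)
    if (length(remaining) == 0) { stopped <- "exhausted"; break }
    cand_acc <- vapply(remaining, function(f) {
      m <- fit_forest(train[, c(selected, f), drop = FALSE], y_tr,
                      learner, seed = seed)
      mean(predict_forest(m, val) == y_va)
    }, 0)
    j <- which.max(cand_acc)               # first max = column order tie-break
    if (length(selected) > 0 && cand_acc[j] - best_acc < tol) {
      stopped <- "tol"
      break
    }
    selected <- c(selected, remaining[j])
    best_acc <- unname(cand_acc[j])
    curve <- c(curve, best_acc)
    if (length(selected) >= max_k) { stopped <- "max_k"; break }
  }
  structure(list(selected = selected, accuracy_curve = curve,
                 stopped_because = stopped, target = target, seed = seed),
            class = "selection_result")
}

#' Default hyperparameter lattice
#'
#' @return data.frame with one row per lattice point (number of trees,
#'   maximum depth with `NA` = unlimited, features-per-split rule).
#' @export
default_grid <- function() {
  expand.grid(n_trees = c(50L, 100L, 200L),
              max_depth = c(NA, 8, 16),
              mtry_rule = c("sqrt", "log2"),
              stringsAsFactors = FALSE)
}

#' Exhaustive grid search over forest hyperparameters
#'
#' Every lattice point is evaluated by training on `train` and scoring
#' accuracy on `val`; ties are broken by first-in-lattice order and the
#' search is reproducible under a fixed seed.
#'
#' @param train,val feature tables restricted to the features in use.
#' @param target label column name.
#' @param features feature columns to train on (default: all).
#' @param grid data.frame lattice as in [default_grid()].
#' @param seed integer seed.
#' @return list of class `grid_search_result` with `best` (a
#'   [learner_config()]), `best_accuracy` and `results` (the grid with
#'   an appended `val_accuracy` column).
#' @export
grid_search <- function(train, val, target = "label",
                        features = feature_columns(train),
                        grid = default_grid(), seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0) stop("empty hyperparameter grid")
  y_tr <- train[[target]]
  y_va <- val[[target]]
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- learner_config(grid$n_trees[i], grid$max_depth[i], grid$mtry_rule[i])
    m <- fit_forest(train[, features, drop = FALSE], y_tr, cfg, seed = seed)
    mean(predict_forest(m, val) == y_va)
  }, 0)
  best_i <- which.max(acc)                  # first-in-lattice tie-break
  results <- cbind(grid, val_accuracy = acc)
  structure(list(best = learner_config(grid$n_trees[best_i],
                                       grid$max_depth[best_i],
                                       grid$mtry_rule[best_i]),
                 best_accuracy = acc[best_i],
                 best_index = best_i,
                 results = results, seed = seed),
            class = "grid_search_result")
}

#' Per-machine feature-selection report
#'
#' Summarizes which moment orders and channels each machine of a
#' trained cascade selected, one row per machine.  For multichannel
#' montages the report has columns machine / moments / channels; for a
#' single-channel montage the channels column is dropped.
#'
#' @param model a [train_cascade()] result.
#' @param path optional CSV destination.
#' @return data.frame (invisibly written to `path` when given).
#' @export
selection_report <- function(model, path = NULL) {
  rows <- lapply(names(model$machines), function(id) {
    sel <- model$machines[[id]]$selection$selected
    ord <- sort(unique(as.integer(sub(".*_m([0-9]+)$", "\\1", sel))))
    chs <- unique(sub("_m[0-9]+$", "", sel))
    data.frame(machine = id,
               moments = paste(ord, collapse = ", "),
               channels = paste(chs, collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  all_ch <- unique(sub("_m[0-9]+$", "", unlist(
    lapply(model$machines, function(m) m$selection$selected))))
  if (length(all_ch) <= 1 && model$n_channels <= 1)
    out$channels <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
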