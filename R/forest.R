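#' Majority vote over an ensemble's tree outputs
#'
#' Returns the most popular label; ties are broken deterministically in
#' favour of the lexicographically smallest label (C-locale order).
#'
#' @param tree_outputs nonempty character vector of per-tree labels.
#' @return the winning label (length-1 character).
#' @export
majority_vote <- function(tree_outputs) {
  if (length(tree_outputs) == 0) stop("majority_vote needs at least one vote")
  u <- sort(unique(as.character(tree_outputs)), method = "radix")
  counts <- vapply(u, function(l) sum(tree_outputs == l), 0L)
  u[which.max(counts)]
}

#' Random-forest learner configuration
#'
#' @param n_trees number of trees (default 100).
#' @param max_depth maximum tree depth; `NA` for unlimited (default).
#' @param mtry_rule features tried per split: `"sqrt"` or `"log2"`.
#' @return list of class `learner_config`.
#' @export
learner_config <- function(n_trees = 100, max_depth = NA,
                           mtry_rule = c("sqrt", "log2")) {
  mtry_rule <- match.arg(mtry_rule)
  structure(list(n_trees = as.integer(n_trees), max_depth = max_depth,
                 mtry_rule = mtry_rule),
            class = "learner_config")
}

mtry_from_rule <- function(rule, p) {
  max(1L, floor(switch(rule, sqrt = sqrt(p), log2 = log2(p))))
}

#' Fit one binary random-forest machine
#'
#' Thin wrapper around `ranger` restricted to the contracts this
#' package relies on: bootstrap-resampled classification trees whose
#' per-tree outputs are aggregated by [majority_vote()] at prediction
#' time, reproducible under a fixed seed.
#'
#' @param x data.frame of features.
#' @param y character or factor vector of labels.
#' @param config a [learner_config()].
#' @param seed integer seed for the forest's randomness.
#' @return list of class `forest_machine`.
#' @export
fit_forest <- function(x, y, config = learner_config(), seed = 1L) {
  stopifnot(nrow(x) == length(y))
  y <- factor(as.character(y))
  if (nlevels(y) < 2)
    stop("training labels contain a single class: ", levels(y))
  depth <- if (is.na(config$max_depth)) 0 else config$max_depth
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = config$n_trees,
    mtry = mtry_from_rule(config$mtry_rule, ncol(x)),
    max.depth = depth,
    seed = as.integer(seed),
    num.threads = 1L,
    classification = TRUE
  )
  structure(list(fit = fit, levels = levels(y), features = colnames(x),
                 config = config, seed = as.integer(seed)),
            class = "forest_machine")
}

#' Predict with a fitted machine via explicit per-tree voting
#'
#' @param machine a [fit_forest()] result.
#' @param newdata data.frame containing at least the machine's feature
#'   columns.
#' @param votes if `TRUE`, also return the per-tree vote matrix.
#' @return character vector of predicted labels (or a list with
#'   `labels` and `votes` when `votes = TRUE`).
#' @export
predict_forest <- function(machine, newdata, votes = FALSE) {
  missing <- setdiff(machine$features, names(newdata))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  nd <- newdata[, machine$features, drop = FALSE]
  pr <- stats::predict(machine$fit, data = nd, predict.all = TRUE,
                       num.threads = 1L)
  idx <- pr$predictions                    # n x n_trees matrix of level indices
  lv <- machine$fit$forest$levels
  n_lv <- length(lv)
  ord <- order(lv, method = "radix")       # lexicographic tie-break
  counts <- matrix(0L, nrow = nrow(idx), ncol = n_lv)
  for (k in seq_len(n_lv))
    counts[, k] <- rowSums(idx == k)
  counts_sorted <- counts[, ord, drop = FALSE]
  win <- max.col(counts_sorted, ties.method = "first")
  labels <- lv[ord][win]
  if (!votes) return(labels)
  list(labels = labels,
       votes = matrix(lv[idx], nrow = nrow(idx)))
}
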