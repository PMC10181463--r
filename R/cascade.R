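# The hierarchical classifier: three levels of binary random-forest
# machines.  Level A separates the body region (hand vs ankle), Level B
# the side (left vs right, one machine per region), Level C the mode
# (real vs imagery, one machine per region-side combination).  Final
# labels compose the three stage outputs, giving the eight activity
# classes.

#' The seven machine definitions of the cascade
#'
#' Machine index convention for Level C: C0 = left hand, C1 = right
#' hand, C2 = left ankle, C3 = right ankle.  Each entry gives the
#' ground-truth subset the machine trains on and the dichotomy it
#' predicts.
#'
#' @return named list of machine specs (`machine_id`, `target`,
#'   `subset` as a named list of required factor values).
#' @export
cascade_machines <- function() {
  list(
    A  = list(machine_id = "A",  target = "region", subset = list()),
    B0 = list(machine_id = "B0", target = "side", subset = list(region = "hand")),
    B1 = list(machine_id = "B1", target = "side", subset = list(region = "ankle")),
    C0 = list(machine_id = "C0", target = "mode",
              subset = list(region = "hand", side = "left")),
    C1 = list(machine_id = "C1", target = "mode",
              subset = list(region = "hand", side = "right")),
    C2 = list(machine_id = "C2", target = "mode",
              subset = list(region = "ankle", side = "left")),
    C3 = list(machine_id = "C3", target = "mode",
              subset = list(region = "ankle", side = "right"))
  )
}

subset_rows <- function(table, subset) {
  keep <- rep(TRUE, nrow(table))
  for (nm in names(subset)) keep <- keep & table[[nm]] == subset[[nm]]
  table[keep, , drop = FALSE]
}

#' Train the three-level cascade of seven machines
#'
#' Each machine trains on the ground-truth-filtered subset of the
#' training rows it specializes in, with its own greedy feature
#' selection followed by a hyperparameter grid search on the selected
#' features (both scored on the matching validation subset), then a
#' final fit with the winning configuration.
#'
#' @param train,val feature tables containing all eight classes.
#' @param selection list of selection settings: `learner` (a
#'   [learner_config()] used during selection), `max_k`, `tol`.
#' @param grid hyperparameter lattice as in [default_grid()]; `NULL`
#'   skips the grid search and keeps the selection learner settings.
#' @param seed integer seed (deterministic training).
#' @return list of class `cascade_model` with the seven trained
#'   machines, the routing convention and the class alphabet.
#' @export
train_cascade <- function(train, val,
                          selection = list(learner = learner_config(50),
                                           max_k = 10, tol = 0.001),
                          grid = default_grid(), seed = 1L) {
  specs <- cascade_machines()
  machines <- vector("list", length(specs))
  names(machines) <- names(specs)
  for (id in names(specs)) {
    sp <- specs[[id]]
    tr <- subset_rows(train, sp$subset)
    va <- subset_rows(val, sp$subset)
    for (tbl in list(tr, va)) {
      cls <- unique(tbl[[sp$target]])
      if (nrow(tbl) == 0 || length(cls) < 2)
        stop(sprintf("machine %s is starved: its %s subset is missing a %s class",
                     id, paste(unlist(sp$subset), collapse = "/"), sp$target))
    }
    sel <- greedy_forward_selection(tr, va, target = sp$target,
                                    learner = selection$learner,
                                    max_k = min(selection$max_k,
                                                length(feature_columns(tr))),
                                    tol = selection$tol, seed = seed)
    if (!is.null(grid)) {
      gs <- grid_search(tr, va, target = sp$target, features = sel$selected,
                        grid = grid, seed = seed)
      best <- gs$best
    } else {
      gs <- NULL
      best <- selection$learner
    }
    fit <- fit_forest(tr[, sel$selected, drop = FALSE], tr[[sp$target]],
                      best, seed = seed)
    machines[[id]] <- list(spec = sp, selection = sel, grid = gs,
                           config = best, fit = fit)
  }
  structure(list(machines = machines,
                 classes = protocol_classes(),
                 n_channels = length(unique(sub("_m[0-9]+$", "",
                                                feature_columns(train)))),
                 seed = as.integer(seed)),
            class = "cascade_model")
}

predict_machine <- function(model, id, rows) {
  predict_forest(model$machines[[id]]$fit, rows)
}

#' Predict eight-way activity labels with a trained cascade
#'
#' Every row is first routed by machine A's region output, then by the
#' matching Level B machine's side output, then by the matching Level C
#' machine's mode output; the final label is the composition of the
#' three stage predictions.
#'
#' @param model a [train_cascade()] result.
#' @param rows feature table (the stage machines' selected feature
#'   columns must all be present).
#' @param stages if `TRUE`, also return the per-stage outputs.
#' @return character vector of labels, or a data.frame with columns
#'   `region`, `side`, `mode`, `label` when `stages = TRUE`.
#' @export
predict_cascade <- function(model, rows, stages = FALSE) {
  n <- nrow(rows)
  region <- predict_machine(model, "A", rows)
  side <- character(n)
  b_route <- c(hand = "B0", ankle = "B1")
  for (reg in names(b_route)) {
    sel <- region == reg
    if (any(sel)) side[sel] <- predict_machine(model, b_route[[reg]],
                                               rows[sel, , drop = FALSE])
  }
  c_route <- c("left-hand" = "C0", "right-hand" = "C1",
               "left-ankle" = "C2", "right-ankle" = "C3")
  mode <- character(n)
  key <- paste(side, region, sep = "-")
  for (k in names(c_route)) {
    sel <- key == k
    if (any(sel)) mode[sel] <- predict_machine(model, c_route[[k]],
                                               rows[sel, , drop = FALSE])
  }
  label <- task_label(region, side, mode)
  if (stages)
    data.frame(region = region, side = side, mode = mode, label = label,
               stringsAsFactors = FALSE)
  else label
}

#' Save a cascade model to a directory
#'
#' Writes one model file per machine plus a JSON manifest recording the
#' routing, selected features, hyperparameters and seed.
#'
#' @param model a `cascade_model`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_cascade <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    classes = model$classes,
    seed = model$seed,
    routing = list(A = "region", B0 = "hand", B1 = "ankle",
                   C0 = "left-hand", C1 = "right-hand",
                   C2 = "left-ankle", C3 = "right-ankle"),
    machines = lapply(model$machines, function(m) list(
      machine_id = m$spec$machine_id,
      target = m$spec$target,
      subset = m$spec$subset,
      selected_features = m$selection$selected,
      accuracy_curve = m$selection$accuracy_curve,
      n_trees = m$config$n_trees,
      max_depth = m$config$max_depth,
      mtry_rule = m$config$mtry_rule))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (id in names(model$machines))
    saveRDS(model$machines[[id]], file.path(dir, paste0("machine_", id, ".rds")))
  invisible(dir)
}

#' Load a cascade model saved by [save_cascade()]
#'
#' @param dir directory written by [save_cascade()].
#' @return a `cascade_model`.
#' @export
load_cascade <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ids <- names(cascade_machines())
  machines <- lapply(ids, function(id)
    readRDS(file.path(dir, paste0("machine_", id, ".rds"))))
  names(machines) <- ids
  structure(list(machines = machines, classes = manifest$classes,
                 n_channels = length(unique(sub("_m[0-9]+$", "", unlist(
                   lapply(machines, function(m) m$selection$selected))))),
                 seed = manifest$seed),
            class = "cascade_model")
}
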