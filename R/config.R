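# Single-file YAML pipeline configuration.

config_defaults <- function() {
  list(
    io = list(dialect = "csv", trigger_label = "TRIGGER"),
    preprocess = list(low_hz = 0.5, high_hz = 59, order = 3,
                      application = "zero_phase", trim_s = 5,
                      win_len_s = 2, overlap_frac = 0.5,
                      threshold = 0.5, min_width_s = 0.25),
    features = list(orders = 1:10, kind = "central",
                    normalize = "recording"),
    selection = list(n_trees = 50, max_k = 10, tol = 0.001),
    grid = list(n_trees = c(50, 100, 200), max_depth = c(NA, 8, 16),
                mtry_rule = c("sqrt", "log2")),
    evaluation = list(framework = 1, seed = 1),
    simulation = list(n_subjects = 9, n_recordings = 2,
                      montage = "vamp16", fs = 512,
                      subject_sd = 0.8, session_sd = 0.25,
                      effect_scale = 1, seed = 1)
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]]))
        stop("configuration key ", full, " must be a mapping")
      base[[k]] <- merge_config(base[[k]], user[[k]], full)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a single YAML file with per-stage blocks (`io`, `preprocess`,
#' `features`, `selection`, `grid`, `evaluation`, `simulation`);
#' unspecified keys take the package defaults and unknown keys are
#' rejected.  See `system.file("extdata", "default_config.yaml",
#' package = "eegcascade")` for a fully commented example.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return list of class `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  structure(cfg, class = "pipeline_config")
}

config_filter_spec <- function(cfg) {
  filter_spec(cfg$preprocess$low_hz, cfg$preprocess$high_hz,
              cfg$preprocess$order, cfg$preprocess$application)
}

config_moment_spec <- function(cfg) {
  moment_spec(unlist(cfg$features$orders), cfg$features$kind,
              cfg$features$normalize)
}

config_grid <- function(cfg) {
  md <- unlist(lapply(cfg$grid$max_depth, function(d)
    if (is.null(d) || (is.character(d) && d %in% c("none", "NA"))) NA
    else as.numeric(d)))
  expand.grid(n_trees = as.integer(unlist(cfg$grid$n_trees)),
              max_depth = md,
              mtry_rule = as.character(unlist(cfg$grid$mtry_rule)),
              stringsAsFactors = FALSE)
}

config_selection <- function(cfg) {
  list(learner = learner_config(cfg$selection$n_trees),
       max_k = cfg$selection$max_k, tol = cfg$selection$tol)
}

config_simulation <- function(cfg, seed = NULL) {
  s <- cfg$simulation
  simulation_config(
    n_subjects = s$n_subjects, n_recordings = s$n_recordings,
    montage = s$montage, fs = s$fs,
    effects = scale_effects(class_effects(), s$effect_scale),
    subject_sd = s$subject_sd, session_sd = s$session_sd,
    seed = if (is.null(seed)) s$seed else seed)
}
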