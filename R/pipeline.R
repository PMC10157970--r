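#' Default decoding task list
#'
#' The standard comparison: each class against every other
#' (class-vs-class) and each class against the within-trial baseline, per
#' condition when conditions are given, pooled otherwise.
#'
#' @param classes class labels present in the data.
#' @param conditions condition labels, or `NULL` to pool conditions.
#' @param mi_window,baseline_window windows in seconds relative to onset.
#' @return list of [task_spec()]s, named `"<contrast>[_<condition>]"`.
#' @export
default_tasks <- function(classes, conditions = NULL,
                          mi_window = c(0, 1.5),
                          baseline_window = c(-3.5, -2)) {
  conds <- if (is.null(conditions)) list(NULL) else as.list(conditions)
  tasks <- list()
  for (cn in conds) {
    tag <- if (is.null(cn)) "" else paste0("_", cn)
    if (length(classes) >= 2L) {
      for (i in seq_len(length(classes) - 1L)) {
        for (j in seq((i + 1L), length(classes))) {
          tasks[[paste0(classes[i], "_vs_", classes[j], tag)]] <-
            task_spec("class_vs_class", classes[i], classes[j],
                      condition = cn, mi_window = mi_window,
                      baseline_window = baseline_window)
        }
      }
    }
    for (cl in classes) {
      tasks[[paste0(cl, "_vs_base", tag)]] <-
        task_spec("class_vs_baseline", cl, condition = cn,
                  mi_window = mi_window, baseline_window = baseline_window)
    }
  }
  tasks
}

#' Pipeline run configuration
#'
#' Bundles the stage parameters of a full synthetic-data run: generator
#' settings, preprocessing, the feature grid (amplitude plus entropy
#' kind x TFR x window combinations) and the decoding setup.
#'
#' @param synth a [synth_config()].
#' @param preprocess a [preprocess_config()].
#' @param tfr_methods TFR tags for entropy features (see [tfr_methods()]).
#' @param entropy_kinds subset of `c("shannon", "renyi")`.
#' @param window_lens entropy window lengths in seconds.
#' @param amplitude include amplitude features.
#' @param n_freq TFR frequency bins.
#' @param tasks list of [task_spec()]s (`NULL` = [default_tasks()] pooled
#'   over conditions).
#' @param n_folds,train_frac cross-validation setup.
#' @param seed master seed; stage seeds are derived deterministically.
#' @return list of class `run_config`.
#' @export
run_config <- function(synth = synth_config(),
                       preprocess = preprocess_config(),
                       tfr_methods = "tfrrpwv",
                       entropy_kinds = "shannon",
                       window_lens = 0.5, amplitude = TRUE, n_freq = 64,
                       tasks = NULL, n_folds = 5, train_frac = 0.75,
                       seed = 1) {
  structure(list(synth = synth, preprocess = preprocess,
                 tfr_methods = tfr_methods, entropy_kinds = entropy_kinds,
                 window_lens = window_lens, amplitude = amplitude,
                 n_freq = n_freq, tasks = tasks, n_folds = n_folds,
                 train_frac = train_frac, seed = seed),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys `synth`, `preprocess`, and the scalar/vector fields of
#' [run_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  args <- list()
  if (!is.null(y$synth)) args$synth <- do.call(synth_config, y$synth)
  if (!is.null(y$preprocess))
    args$preprocess <- do.call(preprocess_config, y$preprocess)
  for (k in setdiff(names(y), c("synth", "preprocess"))) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

.config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(rapply(unclass(cfg), unclass, how = "replace"), tf)
  unname(tools::md5sum(tf))
}

#' Run the full synthetic-data decoding pipeline
#'
#' Per participant: generate the recording, preprocess to amplitude
#' features, derive the configured feature tensors (each trial/channel TFR
#' is computed once and shared across entropy kinds and window lengths),
#' and cross-validate every task on every feature set. Results are grand
#' averaged over participants into a summary table with one row per task
#' and one feature column set per feature configuration.
#'
#' @param cfg a [run_config()].
#' @param out_dir optional directory: per-participant feature tensors are
#'   cached there (keyed by the config hash) and the report is written as
#'   CSV and JSON.
#' @param verbose print stage progress.
#' @return list with `report` (long `data.frame`: task, condition,
#'   feature_kind, tfr, window, accuracy, f1), `per_participant` (decoding
#'   results), and `provenance` (config, hash, seed).
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL,
                         verbose = interactive()) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- .config_hash(cfg)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  feature_names <- character()
  if (cfg$amplitude) feature_names <- "amplitude"
  grid_names <- as.vector(outer(
    sprintf("%s_%s", rep(cfg$tfr_methods, each = length(cfg$entropy_kinds)),
            cfg$entropy_kinds),
    sprintf("w%g", cfg$window_lens), paste, sep = "_"))
  feature_names <- c(feature_names, grid_names)

  tasks <- cfg$tasks
  n_part <- cfg$synth$n_participants
  per_part <- vector("list", n_part)
  for (p in seq_len(n_part)) {
    cache <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("features_p%02d_%s.rds", p, hash)) else NULL
    if (!is.null(cache) && file.exists(cache)) {
      say("participant %d/%d: cached features", p, n_part)
      feats <- readRDS(cache)
    } else {
      say("participant %d/%d: generate + preprocess", p, n_part)
      ds <- generate_dataset(cfg$synth, participants = p)
      epochs <- preprocess_epochs(ds$participants[[1]], cfg$preprocess)
      rm(ds)
      feats <- list()
      if (cfg$amplitude) feats$amplitude <- amplitude_features(epochs)
      say("participant %d/%d: TFR + entropy features", p, n_part)
      grid <- entropy_feature_grid(epochs, methods = cfg$tfr_methods,
                                   kinds = cfg$entropy_kinds,
                                   window_lens = cfg$window_lens,
                                   n_freq = cfg$n_freq)
      feats <- c(feats, grid)
      if (!is.null(cache)) saveRDS(feats, cache)
    }
    if (is.null(tasks)) {
      tasks <- default_tasks(sort(unique(feats[[1]]$labels)),
                             mi_window = feats[[1]]$segment_windows$mi,
                             baseline_window =
                               feats[[1]]$segment_windows$baseline)
    }
    res <- list()
    for (ti in seq_along(tasks)) {
      for (fi in seq_along(feats)) {
        key <- paste(names(tasks)[ti], names(feats)[fi], sep = ".")
        res[[key]] <- tryCatch(
          crossvalidate(feats[[fi]], tasks[[ti]], n_folds = cfg$n_folds,
                        train_frac = cfg$train_frac,
                        seed = cfg$seed + 131L * ti + 7L * fi),
          error = function(e)
            stop("task `", names(tasks)[ti], "` on feature `",
                 names(feats)[fi], "` failed: ", conditionMessage(e)))
      }
    }
    per_part[[p]] <- res
  }

  rows <- list()
  for (ti in seq_along(tasks)) {
    for (fi in seq_along(feature_names)) {
      key <- paste(names(tasks)[ti], feature_names[fi], sep = ".")
      ga <- grand_average(lapply(per_part, `[[`, key))
      sp <- tasks[[ti]]
      fk <- feature_names[fi]
      is_amp <- fk == "amplitude"
      rows[[key]] <- data.frame(
        task = names(tasks)[ti],
        condition = if (is.null(sp$condition)) "all" else sp$condition,
        feature_kind = if (is_amp) "amplitude" else
          sub("^.*_(shannon|renyi)_w.*$", "\\1", fk),
        tfr = if (is_amp) NA_character_ else sub("_(shannon|renyi).*$", "", fk),
        window = if (is_amp) NA_real_ else
          as.numeric(sub("^.*_w", "", fk)),
        accuracy = ga$accuracy, f1 = ga$f1,
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  prov <- list(config_hash = hash, seed = cfg$seed,
               package_version = as.character(utils::packageVersion("tfemi")),
               n_participants = n_part)
  if (!is.null(out_dir)) {
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(report = report, provenance = prov),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, per_participant = per_part, provenance = prov)
}
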