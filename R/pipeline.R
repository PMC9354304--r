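#' Pipeline run configuration
#'
#' Bundles every stage's options into one validated list that round-trips
#' losslessly through YAML. Each stage derives its own seed deterministically
#' from `seed`.
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"edf_dir"`
#'   (read a subjects table of EDF paths).
#' @param group_sizes Simulated cohort sizes (simulate mode).
#' @param subjects_table Path to a subjects TSV (edf_dir mode).
#' @param montage_layout `"full"` or `"reduced"`; ignored when
#'   `montage_path` is given.
#' @param montage_path Optional montage TSV path.
#' @param sampling_rate,duration_s Simulation parameters.
#' @param tar_numerator,duration_rule,min_duration_s Feature/inclusion options.
#' @param selection_runs,selection_threshold,selection_split Wrapper options.
#' @param classifier,neighbors,cv_folds Classifier options.
#' @param tasks Binary tasks to evaluate; subset of
#'   `c("HC-D", "AD-DLB", "AD-LBD", "DLB-PDD")`.
#' @param seed Master seed.
#' @param output_dir Run directory to create.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "edf_dir"),
                       group_sizes = c(HC = 15, AD = 12, DLB = 21, PDD = 17),
                       subjects_table = NULL,
                       montage_layout = "full", montage_path = NULL,
                       sampling_rate = 1024, duration_s = 150,
                       tar_numerator = "high_theta",
                       duration_rule = "combined", min_duration_s = 20,
                       selection_runs = 100, selection_threshold = 0.95,
                       selection_split = 0.7,
                       classifier = "cosine_knn", neighbors = 10, cv_folds = 10,
                       tasks = c("HC-D", "AD-DLB"),
                       seed = 1, output_dir = tempfile("qeegdx-run-")) {
  mode <- match.arg(mode)
  if (mode == "edf_dir" && is.null(subjects_table)) {
    abort("edf_dir mode needs a subjects_table path")
  }
  bad <- setdiff(tasks, c("HC-D", "AD-DLB", "AD-LBD", "DLB-PDD"))
  if (length(bad)) abort(paste("unknown tasks:", paste(bad, collapse = ", ")))
  structure(
    list(
      mode = mode, group_sizes = as.list(group_sizes),
      subjects_table = subjects_table,
      montage_layout = montage_layout, montage_path = montage_path,
      sampling_rate = sampling_rate, duration_s = duration_s,
      tar_numerator = tar_numerator,
      duration_rule = duration_rule, min_duration_s = min_duration_s,
      selection_runs = selection_runs,
      selection_threshold = selection_threshold,
      selection_split = selection_split,
      classifier = classifier, neighbors = neighbors, cv_folds = cv_folds,
      tasks = tasks, seed = as.integer(seed), output_dir = output_dir
    ),
    class = "run_config"
  )
}

#' Write or read a run configuration (YAML)
#' @param config A [run_config()].
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$group_sizes <- unlist(vals$group_sizes)
  vals$tasks <- unlist(vals$tasks)
  do.call(run_config, vals)
}

#' Read and validate a subjects table
#'
#' Expects a TSV with columns `subject_id`, `group`, `ec_path`, `eo_path`
#' (either path may be empty for a single-condition subject) plus optional
#' numeric clinical columns. Unknown group labels and duplicate ids are
#' rejected with the offending rows named.
#'
#' @param path TSV path.
#' @return Validated tibble manifest.
#' @export
read_subjects_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("subject_id", "group", "ec_path", "eo_path")
  if (!all(req %in% names(tab))) {
    abort(paste("subjects table must have columns:", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(tab$subject_id)) {
    abort(paste(
      "duplicate subject ids:",
      paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", ")
    ))
  }
  bad <- !tab$group %in% c("HC", "AD", "DLB", "PDD")
  if (any(bad)) {
    abort(paste(
      "unknown group label in rows:",
      paste(which(bad), collapse = ", "),
      "(", paste(unique(tab$group[bad]), collapse = ", "), ")"
    ))
  }
  tab
}

# load a cohort tibble (subject_id, group, ec, eo) from a subjects table
.load_edf_cohort <- function(manifest) {
  read_or_null <- function(p, cond) {
    if (is.na(p) || !nzchar(p)) return(NULL)
    if (!file.exists(p)) abort(paste("missing EDF file:", p))
    read_edf(p, condition = cond)
  }
  tibble::tibble(
    subject_id = manifest$subject_id,
    group = manifest$group,
    ec = purrr::map(manifest$ec_path, read_or_null, cond = "EC"),
    eo = purrr::map(manifest$eo_path, read_or_null, cond = "EO")
  )
}

#' Run the full pipeline
#'
#' Executes cohort input (simulation or EDF reading), the minimum-duration
#' inclusion rule, feature extraction, group statistics, wrapper feature
#' selection and cross-validated classification for the configured tasks,
#' writing every artefact into the run directory: `features.tsv`,
#' `group_stats.tsv`, `selection_<task>.json`, `cv_metrics.json` /
#' `cv_metrics.tsv`, `exclusions.tsv`, `log.txt` and `manifest.json`.
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly; artefact paths are listed in
#'   its `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  log_lines <- c(sprintf(
    "qeegdx %s | mode=%s | seed=%d | %s",
    as.character(utils::packageVersion("qeegdx")),
    config$mode, config$seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  ))
  tick <- function(msg) log_lines <<- c(log_lines, msg)

  montage <- if (!is.null(config$montage_path)) {
    read_montage(config$montage_path)
  } else {
    default_montage(config$montage_layout)
  }

  if (config$mode == "simulate") {
    spec <- cohort_spec(
      group_sizes = unlist(config$group_sizes),
      sampling_rate = config$sampling_rate, duration_s = config$duration_s,
      montage = montage, seed = config$seed
    )
    cohort <- make_cohort(spec)
    tick(sprintf("simulated cohort: %d subjects", nrow(cohort)))
  } else {
    manifest_in <- read_subjects_table(config$subjects_table)
    cohort <- .load_edf_cohort(manifest_in)
    tick(sprintf("loaded %d subjects from %s", nrow(cohort), config$subjects_table))
  }

  # minimum-duration inclusion rule
  dur <- function(r) if (is.null(r)) 0 else recording_duration(r)
  ec_d <- purrr::map_dbl(cohort$ec, dur)
  eo_d <- purrr::map_dbl(cohort$eo, dur)
  ok <- purrr::map2_lgl(ec_d, eo_d, passes_duration_rule,
    minimum = config$min_duration_s, rule = config$duration_rule
  )
  exclusions <- tibble::tibble(
    subject_id = cohort$subject_id[!ok],
    reason = sprintf(
      "below_minimum_duration_ec%.1fs_eo%.1fs", ec_d[!ok], eo_d[!ok]
    )
  )
  readr::write_tsv(exclusions, out("exclusions.tsv"), progress = FALSE)
  if (any(!ok)) {
    tick(sprintf(
      "excluded %d subjects (minimum-duration rule): %s",
      sum(!ok), paste(cohort$subject_id[!ok], collapse = ", ")
    ))
  }
  cohort <- cohort[ok, ]
  if (!nrow(cohort)) abort("no subjects pass the inclusion rule")

  features <- build_feature_table(cohort, montage,
    tar_numerator = config$tar_numerator
  )
  write_feature_table(features, out("features.tsv"))
  tick(sprintf(
    "feature table: %d subjects x %d features",
    nrow(features), length(feature_columns(features))
  ))

  stats_tab <- NULL
  if (length(unique(features$group)) >= 2 && min(table(features$group)) >= 3) {
    stats_tab <- compare_features(features)
    readr::write_tsv(stats_tab, out("group_stats.tsv"), progress = FALSE)
    tick("group statistics written")
  }

  task_labels <- function(task, grp) {
    switch(task,
      "HC-D" = list(
        keep = rep(TRUE, length(grp)),
        y = ifelse(grp == "HC", "HC", "D"), pos = "D"
      ),
      "AD-DLB" = list(keep = grp %in% c("AD", "DLB"), y = grp, pos = "DLB"),
      "AD-LBD" = list(
        keep = grp != "HC",
        y = ifelse(grp == "AD", "AD", "LBD"), pos = "LBD"
      ),
      "DLB-PDD" = list(keep = grp %in% c("DLB", "PDD"), y = grp, pos = "PDD")
    )
  }

  cols <- feature_columns(features)
  cv_results <- list()
  for (task in config$tasks) {
    tl <- task_labels(task, features$group)
    sub <- features[tl$keep, ]
    ysub <- tl$y[tl$keep]
    if (length(unique(ysub)) < 2 || min(table(ysub)) < 4) {
      tick(sprintf("task %s skipped: too few subjects", task))
      next
    }
    x <- as.matrix(sub[cols])
    keep_rows <- complete.cases(x)
    x <- x[keep_rows, , drop = FALSE]
    yy <- ysub[keep_rows]

    sel <- wrapper_select(x, yy,
      n_runs = config$selection_runs,
      train_fraction = config$selection_split,
      threshold = config$selection_threshold,
      neighbors = config$neighbors,
      seed = config$seed + match(task, config$tasks)
    )
    write_selection_report(
      sel, out(sprintf("selection_%s.json", task)),
      out(sprintf("selection_%s.tsv", task))
    )
    use_cols <- if (length(sel$retained)) sel$retained else cols
    tick(sprintf(
      "task %s: %d features retained by selection", task, length(sel$retained)
    ))

    cfg <- classifier_config(config$classifier,
      neighbors = config$neighbors,
      cv_folds = config$cv_folds, seed = config$seed
    )
    cv_results[[task]] <- cross_validate(
      cfg, x[, use_cols, drop = FALSE], yy,
      positive_class = tl$pos, task = task
    )
  }

  if (length(cv_results)) {
    cv_tab <- purrr::map_dfr(cv_results, tidy)
    readr::write_tsv(cv_tab, out("cv_metrics.tsv"), progress = FALSE)
    jsonlite::write_json(
      purrr::map(cv_results, function(cv) {
        cv[c(
          "task", "n", "accuracy", "sensitivity", "specificity",
          "ci_accuracy", "ci_sensitivity", "ci_specificity",
          "weighted_average_auc"
        )]
      }),
      out("cv_metrics.json"),
      auto_unbox = TRUE, digits = NA
    )
  }

  if (all(c("HC", "AD", "DLB", "PDD") %in% features$group) &&
    min(table(features$group)) >= 4) {
    cfg <- classifier_config(config$classifier,
      neighbors = config$neighbors,
      cv_folds = config$cv_folds, seed = config$seed
    )
    ts <- two_step_classify(cfg, features, columns = cols, seed = config$seed)
    jsonlite::write_json(tidy(ts), out("two_step.json"),
      auto_unbox = TRUE, digits = NA
    )
    tick(sprintf("two-step classification: %s", ts$status))
  }

  write_run_config(config, out("config.yaml"))
  writeLines(log_lines, out("log.txt"))
  artefacts <- setdiff(list.files(config$output_dir), "manifest.json")
  jsonlite::write_json(
    list(
      package_version = as.character(utils::packageVersion("qeegdx")),
      seed = config$seed, mode = config$mode, files = artefacts
    ),
    out("manifest.json"),
    auto_unbox = TRUE
  )
  invisible(config$output_dir)
}
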