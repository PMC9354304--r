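#' Repeated wrapper feature selection with NCA ranking
#'
#' The selection protocol behind the retained feature sets: for each of
#' `n_runs` runs the data is split into stratified train/test parts,
#' features are z-scored with training statistics, an NCA model ranks them
#' by weight, and a greedy forward pass in rank order keeps a feature iff
#' adding it strictly improves the held-out accuracy of the reference
#' cosine-KNN classifier. The pass starts from the empty model (accuracy 0),
#' so the top-ranked feature always enters and every later feature must earn
#' its place.
#' Features picked in at least `threshold * n_runs` runs are retained.
#'
#' @param x Feature matrix or data frame (samples x features).
#' @param y Class labels.
#' @param n_runs Number of simulated runs.
#' @param train_fraction Stratified split fraction.
#' @param threshold Retention threshold as a fraction of runs.
#' @param lambda NCA ridge penalty; `NULL` selects it once for the dataset
#'   with [select_nca_lambda()].
#' @param neighbors Neighbour count of the reference cosine KNN.
#' @param seed Master seed; per-run split seeds derive from it.
#' @return A `qeeg_selection` object with `pick_counts` (tibble
#'   `feature`, `picks`), `retained`, `runs` (per-run log) and the settings.
#' @export
wrapper_select <- function(x, y, n_runs = 100, train_fraction = 0.7,
                           threshold = 0.95, lambda = NULL, neighbors = 10,
                           seed = 1) {
  x <- as.matrix(x)
  y <- as.character(y)
  nf <- ncol(x)
  feature_names <- colnames(x) %||% paste0("f", seq_len(nf))
  colnames(x) <- feature_names
  if (min(table(y)) < 4) abort("too few samples per class for a stratified split")

  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1, n_runs)
  if (is.null(lambda)) {
    mu <- colMeans(x)
    sig <- apply(x, 2, sd)
    sig[sig == 0] <- 1
    lambda <- select_nca_lambda(sweep(sweep(x, 2, mu), 2, sig, "/"), y,
      seed = run_seeds[1]
    )
  }

  cfg <- classifier_config("cosine_knn", neighbors = neighbors)
  runs <- purrr::map(seq_len(n_runs), function(r) {
    tr <- stratified_split(y, train_fraction, seed = run_seeds[r])
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
      abort("degenerate split: a class is absent from train or test")
    }
    mu <- colMeans(x[tr, , drop = FALSE])
    sig <- apply(x[tr, , drop = FALSE], 2, sd)
    sig[sig == 0] <- 1
    ztr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sig, "/")
    zte <- sweep(sweep(x[!tr, , drop = FALSE], 2, mu), 2, sig, "/")

    fit <- nca_fit(ztr, y[tr], lambda = lambda)
    rank_order <- order(fit$weights, decreasing = TRUE)

    pos <- sort(unique(y))[1]
    best_acc <- 0 # empty model: the top-ranked feature always enters
    picked <- integer(0)
    for (f in rank_order) {
      cand <- c(picked, f)
      out <- tryCatch(
        fit_predict(cfg, ztr[, cand, drop = FALSE], y[tr],
          zte[, cand, drop = FALSE],
          positive_class = pos
        ),
        error = function(e) NULL
      )
      if (is.null(out)) next
      acc <- mean(out$labels == y[!tr])
      if (acc > best_acc) {
        picked <- cand
        best_acc <- acc
      }
    }
    list(
      seed = run_seeds[r], picked = feature_names[sort(picked)],
      accuracy = best_acc
    )
  })

  picks <- table(factor(unlist(purrr::map(runs, "picked")), levels = feature_names))
  pick_counts <- tibble::tibble(
    feature = feature_names,
    picks = as.integer(picks)
  )
  retained <- pick_counts$feature[pick_counts$picks >= threshold * n_runs]

  structure(
    list(
      pick_counts = pick_counts, retained = retained,
      n_runs = n_runs, threshold = threshold, lambda = lambda,
      train_fraction = train_fraction, neighbors = neighbors, seed = seed,
      runs = tibble::tibble(
        run = seq_len(n_runs),
        seed = purrr::map_int(runs, ~ as.integer(.x$seed)),
        picked = purrr::map(runs, "picked"),
        accuracy = purrr::map_dbl(runs, "accuracy")
      )
    ),
    class = "qeeg_selection"
  )
}

#' @export
print.qeeg_selection <- function(x, ...) {
  cat(sprintf(
    "<qeeg_selection> %d runs, threshold %.0f%%, lambda %.4g\n",
    x$n_runs, 100 * x$threshold, x$lambda
  ))
  cat(
    "  retained:",
    if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)", "\n"
  )
  invisible(x)
}

#' Serialize a selection report
#'
#' Writes the report as JSON (settings, pick counts, retained set, per-run
#' log) and, optionally, the pick-count bar-chart data as TSV.
#'
#' @param selection A `qeeg_selection`.
#' @param path Output JSON path.
#' @param tsv_path Optional TSV path for the pick counts.
#' @export
write_selection_report <- function(selection, path, tsv_path = NULL) {
  payload <- list(
    n_runs = selection$n_runs, threshold = selection$threshold,
    lambda = selection$lambda, train_fraction = selection$train_fraction,
    neighbors = selection$neighbors, seed = selection$seed,
    pick_counts = selection$pick_counts, retained = selection$retained,
    runs = list(
      seed = selection$runs$seed, accuracy = selection$runs$accuracy,
      picked = selection$runs$picked
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    readr::write_tsv(selection$pick_counts, tsv_path, progress = FALSE)
  }
  invisible(path)
}
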