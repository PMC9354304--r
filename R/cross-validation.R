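#' Stratified k-fold cross-validation with pooled metrics
#'
#' Runs the configured classifier over seeded stratified folds and computes
#' accuracy, sensitivity (recall of the positive class) and specificity
#' (recall of the other class) from the pooled out-of-fold confusion table,
#' each with its 95% Wald half-width (n = task size for accuracy, class
#' sizes for sensitivity/specificity). The weighted-average AUC is the
#' prevalence-weighted mean of the per-class trapezoidal AUCs on pooled
#' scores. If the smallest class has fewer members than `cv_folds`, the fold
#' count is reduced with a warning.
#'
#' @param config A [classifier_config()].
#' @param x Feature matrix or data frame (samples x features).
#' @param y Binary class labels.
#' @param positive_class Label treated as positive.
#' @param task Task name stored on the result (e.g. `"HC-D"`).
#' @param folds Optional precomputed fold assignment (integer vector); when
#'   supplied it overrides the seeded assignment, which lets callers reuse
#'   identical folds across feature sets.
#' @return A `qeeg_cv` object; see [tidy.qeeg_cv()] and [glance.qeeg_cv()].
#' @export
cross_validate <- function(config, x, y, positive_class, task = "task",
                           folds = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) abort("cross_validate expects a binary task")
  if (!positive_class %in% classes) abort("positive_class not found in labels")
  negative_class <- setdiff(classes, positive_class)

  k <- config$cv_folds
  min_class <- min(table(y))
  if (min_class < k) {
    k <- max(2, min_class)
    warn(sprintf("reducing folds to %d (smallest class has %d members)", k, min_class))
  }
  if (is.null(folds)) folds <- make_stratified_folds(y, k, seed = config$seed)

  pred <- character(length(y))
  score <- numeric(length(y))
  for (f in sort(unique(folds))) {
    te <- folds == f
    if (length(unique(y[!te])) < 2) abort("fold with a single training class")
    out <- fit_predict(
      config, x[!te, , drop = FALSE], y[!te],
      x[te, , drop = FALSE], positive_class
    )
    pred[te] <- out$labels
    score[te] <- out$scores
  }

  n <- length(y)
  n_pos <- sum(y == positive_class)
  n_neg <- n - n_pos
  tp <- sum(pred == positive_class & y == positive_class)
  tn <- sum(pred == negative_class & y == negative_class)
  accuracy <- (tp + tn) / n
  sensitivity <- tp / n_pos
  specificity <- tn / n_neg
  auc_pos <- auc_score(score, y, positive_class)
  auc_neg <- auc_score(-score, y, negative_class)
  weighted_auc <- (n_pos * auc_pos + n_neg * auc_neg) / n

  structure(
    list(
      task = task, config = config,
      positive_class = positive_class, negative_class = negative_class,
      n = n, n_pos = n_pos, n_neg = n_neg,
      accuracy = accuracy, sensitivity = sensitivity, specificity = specificity,
      ci_accuracy = wald_ci_halfwidth(accuracy, n),
      ci_sensitivity = wald_ci_halfwidth(sensitivity, n_pos),
      ci_specificity = wald_ci_halfwidth(specificity, n_neg),
      weighted_average_auc = weighted_auc,
      folds = folds,
      predictions = tibble::tibble(
        truth = y, predicted = pred, score = score, fold = folds
      )
    ),
    class = "qeeg_cv"
  )
}

#' @export
print.qeeg_cv <- function(x, ...) {
  cat(sprintf(
    "<qeeg_cv> %s (%s, %d-fold): accuracy %.2f +/- %.2f | spec %.2f +/- %.2f | sens %.2f +/- %.2f | wAUC %.2f\n",
    x$task, x$config$kind, length(unique(x$folds)),
    x$accuracy, x$ci_accuracy, x$specificity, x$ci_specificity,
    x$sensitivity, x$ci_sensitivity, x$weighted_average_auc
  ))
  invisible(x)
}

#' Two-step multi-class classification
#'
#' Step 1 filters healthy controls from non-healthy participants by
#' cross-validated HC-vs-rest classification. Step 2 takes the subjects
#' predicted non-healthy at step 1 (by default; set `step2_on = "true"` to
#' use the true non-healthy subjects) and evaluates each dementia group
#' one-vs-rest within that set, reusing the same master seed. Subjects
#' predicted healthy at step 1 appear in no step-2 evaluation.
#'
#' @param config A [classifier_config()].
#' @param features A `qeeg_features` tibble with all four groups.
#' @param columns Feature columns to use; default all.
#' @param seed Master seed; step seeds derive from it.
#' @param step2_on `"predicted"` or `"true"` non-healthy membership.
#' @return A `qeeg_two_step` object: `step1` (a `qeeg_cv`), `step2` (named
#'   list of `qeeg_cv` per dementia group) and `status`.
#' @export
two_step_classify <- function(config, features, columns = NULL, seed = 1,
                              step2_on = c("predicted", "true")) {
  step2_on <- match.arg(step2_on)
  if (!all(c("HC", "AD", "DLB", "PDD") %in% features$group)) {
    abort("all four groups must be present")
  }
  if (is.null(columns)) columns <- feature_columns(features)
  x <- as.matrix(features[columns])
  keep <- complete.cases(x)
  x <- x[keep, , drop = FALSE]
  grp <- features$group[keep]

  y1 <- ifelse(grp == "HC", "HC", "D")
  cfg1 <- config
  cfg1$seed <- seed
  step1 <- cross_validate(cfg1, x, y1, positive_class = "D", task = "HC-D")

  nh <- if (step2_on == "predicted") {
    step1$predictions$predicted == "D"
  } else {
    grp != "HC"
  }
  if (!any(nh)) {
    return(structure(
      list(step1 = step1, step2 = list(), status = "step2_skipped_all_predicted_HC"),
      class = "qeeg_two_step"
    ))
  }
  x2 <- x[nh, , drop = FALSE]
  g2 <- grp[nh]
  step2 <- list()
  for (dg in c("AD", "DLB", "PDD")) {
    if (sum(g2 == dg) < 2 || sum(g2 != dg) < 2) next
    y2 <- ifelse(g2 == dg, dg, "rest")
    cfg2 <- config
    cfg2$seed <- seed + match(dg, c("AD", "DLB", "PDD"))
    step2[[dg]] <- cross_validate(cfg2, x2, y2,
      positive_class = dg,
      task = paste0(dg, "-rest")
    )
  }
  structure(
    list(step1 = step1, step2 = step2, status = "ok"),
    class = "qeeg_two_step"
  )
}

#' @export
print.qeeg_two_step <- function(x, ...) {
  cat("<qeeg_two_step> step 1:\n  ")
  print(x$step1)
  if (length(x$step2)) {
    cat("step 2 (among predicted non-healthy):\n")
    for (cv in x$step2) {
      cat("  ")
      print(cv)
    }
  } else {
    cat("step 2:", x$status, "\n")
  }
  invisible(x)
}

#' Compare classification over alternative feature sets
#'
#' Cross-validates the same task once per feature set while reusing an
#' identical fold assignment, so metric differences are attributable to the
#' features rather than the partitioning. Rows with missing values in any
#' requested feature set are dropped listwise (with a warning giving the
#' count).
#'
#' @param config A [classifier_config()].
#' @param features A `qeeg_features` tibble.
#' @param feature_sets Named list of column-name vectors, e.g.
#'   `list(EC_only = ..., EC_EO = ...)`.
#' @param labels Binary task labels, one per row of `features`.
#' @param positive_class Positive label.
#' @return Named list of `qeeg_cv`, one per feature set, each sharing the
#'   same `folds`.
#' @export
compare_feature_sets <- function(config, features, feature_sets, labels,
                                 positive_class) {
  if (!length(feature_sets) || any(!lengths(feature_sets))) {
    abort("feature sets must be non-empty")
  }
  all_cols <- unique(unlist(feature_sets))
  if (!all(all_cols %in% names(features))) {
    abort("unknown feature columns requested")
  }
  keep <- complete.cases(features[all_cols])
  if (any(!keep)) {
    warn(sprintf("dropping %d rows with missing feature values", sum(!keep)))
  }
  y <- as.character(labels)[keep]
  k <- min(config$cv_folds, min(table(y)))
  folds <- make_stratified_folds(y, max(2, k), seed = config$seed)
  purrr::imap(feature_sets, function(cols, nm) {
    cross_validate(config, features[keep, cols, drop = FALSE], y,
      positive_class = positive_class, task = nm, folds = folds
    )
  })
}
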