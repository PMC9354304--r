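#' Tidy an NCA model
#'
#' @param x A `qeeg_nca` object.
#' @param ... Unused.
#' @return Tibble: `feature`, `weight`, sorted by descending weight.
#' @export
tidy.qeeg_nca <- function(x, ...) {
  out <- tibble::tibble(feature = names(x$weights), weight = unname(x$weights))
  dplyr::arrange(out, dplyr::desc(.data$weight))
}

#' @rdname tidy.qeeg_nca
#' @export
glance.qeeg_nca <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_features = x$n_features, lambda = x$lambda,
    objective = utils::tail(x$objective_trace, 1),
    iterations = length(x$objective_trace) - 1,
    converged = x$converged
  )
}

#' Tidy cross-validation metrics
#'
#' @param x A `qeeg_cv` object.
#' @param ... Unused.
#' @return One-row tibble with the pooled metrics and their 95% Wald
#'   half-widths, matching the layout of a classification results table.
#' @export
tidy.qeeg_cv <- function(x, ...) {
  tibble::tibble(
    task = x$task, classifier = x$config$kind, n = x$n,
    accuracy = x$accuracy, ci_accuracy = x$ci_accuracy,
    specificity = x$specificity, ci_specificity = x$ci_specificity,
    sensitivity = x$sensitivity, ci_sensitivity = x$ci_sensitivity,
    weighted_average_auc = x$weighted_average_auc
  )
}

#' @rdname tidy.qeeg_cv
#' @export
glance.qeeg_cv <- function(x, ...) {
  tibble::tibble(
    task = x$task, n = x$n, folds = length(unique(x$folds)),
    accuracy = x$accuracy, weighted_average_auc = x$weighted_average_auc
  )
}

#' Tidy a two-step classification report
#'
#' @param x A `qeeg_two_step` object.
#' @param ... Unused.
#' @return Tibble with one row for step 1 and one per step-2 group.
#' @export
tidy.qeeg_two_step <- function(x, ...) {
  rows <- c(
    list(dplyr::mutate(tidy(x$step1), step = 1L, .before = 1)),
    purrr::map(x$step2, ~ dplyr::mutate(tidy(.x), step = 2L, .before = 1))
  )
  dplyr::bind_rows(rows)
}

#' Tidy a selection report
#'
#' @param x A `qeeg_selection` object.
#' @param ... Unused.
#' @return Tibble: `feature`, `picks`, `pick_fraction`, `retained`.
#' @export
tidy.qeeg_selection <- function(x, ...) {
  dplyr::mutate(x$pick_counts,
    pick_fraction = .data$picks / x$n_runs,
    retained = .data$feature %in% x$retained
  )
}

#' @rdname tidy.qeeg_selection
#' @export
glance.qeeg_selection <- function(x, ...) {
  tibble::tibble(
    n_runs = x$n_runs, threshold = x$threshold, lambda = x$lambda,
    n_retained = length(x$retained),
    mean_run_accuracy = mean(x$runs$accuracy)
  )
}

#' Tidy a group comparison
#'
#' @param x A `qeeg_group_comparison` object.
#' @param ... Unused.
#' @return Tibble of the six pairwise comparisons with raw and
#'   Bonferroni-corrected p-values.
#' @export
tidy.qeeg_group_comparison <- function(x, ...) {
  dplyr::mutate(x$pairwise,
    feature = x$feature_name, test = x$test_used,
    .before = 1
  )
}

#' @rdname tidy.qeeg_group_comparison
#' @export
glance.qeeg_group_comparison <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_name, test_used = x$test_used,
    omnibus_statistic = x$omnibus_statistic, omnibus_p = x$omnibus_p
  )
}
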