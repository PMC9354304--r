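#' Pick-count bar chart for a selection report
#'
#' Bar chart of how often each feature was picked over the wrapper runs,
#' with the retention threshold drawn as a dashed line.
#'
#' @param object A `qeeg_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qeeg_selection <- function(object, ...) {
  d <- tidy(object)
  d$feature <- factor(d$feature, levels = d$feature[order(-d$picks)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$picks,
    fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      yintercept = object$threshold * object$n_runs,
      linetype = "dashed"
    ) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65", `TRUE` = "#2c7fb8")) +
    ggplot2::labs(
      x = NULL, y = sprintf("times picked (of %d runs)", object$n_runs),
      fill = "retained"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Pooled ROC curve for a cross-validation result
#'
#' @param object A `qeeg_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qeeg_cv <- function(object, ...) {
  p <- object$predictions
  thr <- sort(unique(p$score), decreasing = TRUE)
  roc <- purrr::map_dfr(c(Inf, thr, -Inf), function(t) {
    tibble::tibble(
      fpr = mean(p$score[p$truth != object$positive_class] >= t),
      tpr = mean(p$score[p$truth == object$positive_class] >= t)
    )
  })
  ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf(
        "%s: weighted AUC %.2f", object$task, object$weighted_average_auc
      )
    ) +
    ggplot2::theme_minimal()
}

#' Boxplots of the EC/EO DFV reactivity ratio by group
#'
#' Mirrors the classic reactivity figure: one box per diagnostic group,
#' faceted by cortical region, with the no-reactivity line at ratio 1.
#'
#' @param features A `qeeg_features` tibble.
#' @param regions Regions to include (default all present).
#' @return A ggplot object.
#' @export
plot_dfv_ratio <- function(features, regions = c("F", "C", "T", "P", "O")) {
  cols <- paste0(regions, "_DFV_ECEO_ratio")
  cols <- cols[cols %in% names(features)]
  if (!length(cols)) abort("no DFV ratio columns in the feature table")
  long <- tidyr::pivot_longer(
    features[c("subject_id", "group", cols)], dplyr::all_of(cols),
    names_to = "region", values_to = "ratio"
  )
  long$region <- factor(sub("_DFV_ECEO_ratio", "", long$region), levels = regions)
  long$group <- factor(long$group, levels = c("HC", "AD", "DLB", "PDD"))
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$ratio, fill = .data$group)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~region, nrow = 1) +
    ggplot2::labs(x = NULL, y = "DFV ratio (EC / EO)") +
    ggplot2::theme_minimal()
}
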