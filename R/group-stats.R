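#' Per-group normality screen
#'
#' Automated stand-in for visual Q-Q inspection: a Shapiro-Wilk test per
#' group at level `alpha`. Groups with fewer than 3 observations or zero
#' variance are flagged non-assessable (`NA`).
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector, same length.
#' @param alpha Significance level below which a group is flagged non-normal.
#' @return Tibble: `group`, `n`, `normal` (logical, `NA` = non-assessable).
#' @export
normality_screen <- function(values, groups, alpha = 0.05) {
  purrr::map_dfr(split(values, groups), function(x) {
    x <- x[is.finite(x)]
    flag <- if (length(x) < 3 || length(x) > 5000 || sd(x) == 0) {
      NA
    } else {
      shapiro.test(x)$p.value >= alpha
    }
    tibble::tibble(n = length(x), normal = flag)
  }, .id = "group")
}

#' Four-group comparison of one feature
#'
#' One-way ANOVA across the four diagnostic groups when every group passes
#' the normality screen, otherwise the Kruskal-Wallis test. Post hoc pairwise
#' comparisons (unpaired two-sample t-tests, or rank-sum tests on the
#' non-parametric branch) are Bonferroni-corrected over the 6 group pairs.
#'
#' @param values Numeric vector of feature values.
#' @param groups Group labels (4 distinct values expected).
#' @param feature_name Stored on the result for reporting.
#' @param alpha_normality Level of the Shapiro-Wilk screen.
#' @param var_equal Use the classic pooled-variance t-test for post hoc
#'   comparisons (default) or Welch.
#' @param force_test Force `"anova"` or `"kruskal_wallis"` instead of letting
#'   the normality screen decide.
#' @return A `qeeg_group_comparison` object; see [tidy.qeeg_group_comparison()].
#' @export
compare_groups <- function(values, groups, feature_name = "feature",
                           alpha_normality = 0.05, var_equal = TRUE,
                           force_test = NULL) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  lv <- unique(groups)
  if (length(lv) < 2) abort("need at least 2 non-empty groups")
  counts <- table(groups)
  if (any(counts < 2)) abort("every group needs at least 2 observations")

  screen <- normality_screen(values, groups, alpha = alpha_normality)
  test_used <- if (!is.null(force_test)) {
    match.arg(force_test, c("anova", "kruskal_wallis"))
  } else if (all(screen$normal %in% TRUE)) "anova" else "kruskal_wallis"

  g <- factor(groups)
  if (test_used == "anova") {
    fit <- aov(values ~ g)
    tab <- anova(fit)
    omnibus_stat <- tab$`F value`[1]
    omnibus_p <- tab$`Pr(>F)`[1]
  } else {
    kw <- kruskal.test(values, g)
    omnibus_stat <- unname(kw$statistic)
    omnibus_p <- kw$p.value
  }

  pairs <- utils::combn(sort(lv), 2)
  n_pairs <- ncol(pairs)
  pairwise <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    a <- values[groups == pairs[1, i]]
    b <- values[groups == pairs[2, i]]
    p_raw <- if (test_used == "anova") {
      t.test(a, b, var.equal = var_equal)$p.value
    } else {
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    }
    tibble::tibble(
      group_i = pairs[1, i], group_j = pairs[2, i],
      p_raw = p_raw, p_corrected = min(1, n_pairs * p_raw)
    )
  })

  structure(
    list(
      feature_name = feature_name, test_used = test_used,
      omnibus_statistic = omnibus_stat, omnibus_p = omnibus_p,
      pairwise = pairwise, normality = screen
    ),
    class = "qeeg_group_comparison"
  )
}

#' @export
print.qeeg_group_comparison <- function(x, ...) {
  cat(sprintf(
    "<qeeg_group_comparison> %s: %s, omnibus stat %.4g, p = %.3g\n",
    x$feature_name, x$test_used, x$omnibus_statistic, x$omnibus_p
  ))
  sig <- x$pairwise[x$pairwise$p_corrected < 0.05, ]
  if (nrow(sig)) {
    cat(
      "  significant pairs (corrected p < 0.05):",
      paste(sig$group_i, sig$group_j, sep = "-", collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' Group comparisons for every feature column
#'
#' Applies [compare_groups()] to each feature column of a feature table and
#' returns a wide tibble mirroring a supplementary-statistics layout: one
#' row per feature with the omnibus p-value and the six Bonferroni-corrected
#' pairwise p-values. No correction is applied across features; correction
#' is within each feature's post hoc family only.
#'
#' @param features A `qeeg_features` tibble (or any data frame with a
#'   `group` column).
#' @param columns Feature columns to test; defaults to all numeric feature
#'   columns.
#' @param ... Passed to [compare_groups()].
#' @return Tibble: `feature`, `test_used`, `omnibus_statistic`, `omnibus_p`,
#'   and `p_<A>_vs_<B>` corrected pairwise columns.
#' @export
compare_features <- function(features, columns = NULL, ...) {
  if (is.null(columns)) {
    columns <- setdiff(names(features), c("subject_id", "group"))
    columns <- columns[vapply(features[columns], is.numeric, logical(1))]
  }
  purrr::map_dfr(columns, function(col) {
    res <- compare_groups(features[[col]], features$group, feature_name = col, ...)
    pw <- setNames(
      res$pairwise$p_corrected,
      paste0("p_", res$pairwise$group_i, "_vs_", res$pairwise$group_j)
    )
    dplyr::bind_cols(
      tibble::tibble(
        feature = col, test_used = res$test_used,
        omnibus_statistic = res$omnibus_statistic, omnibus_p = res$omnibus_p
      ),
      tibble::as_tibble(as.list(pw))
    )
  })
}
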