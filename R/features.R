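#' qEEG features for a single recording
#'
#' Runs segmentation, per-window spectra, and the spectral feature set
#' (five-band relative power, DF, DFV, TAR) per channel, then aggregates
#' over cortical regions. Preprocessing (baseline, band-pass, average
#' reference) is applied first unless `preprocess = FALSE` (useful when the
#' input is already conditioned or purely synthetic).
#'
#' @param rec An [eeg_recording()].
#' @param montage Montage covering the recording's channels.
#' @param preprocess Apply [preprocess_recording()] first?
#' @param tar_numerator Passed to [theta_alpha_ratio()].
#' @param nfft FFT length for [compute_spectra()].
#' @param drop_reference Passed to [preprocess_recording()].
#' @return Tibble: `region`, `delta`, `theta`, `high_theta`, `alpha`, `beta`,
#'   `DF`, `DFV`, `TAR` (one row per region).
#' @export
recording_features <- function(rec, montage, preprocess = TRUE,
                               tar_numerator = "high_theta", nfft = 8192,
                               drop_reference = "Fz") {
  if (preprocess) {
    rec <- preprocess_recording(rec, montage, drop_reference = drop_reference)
  }
  spectra <- compute_spectra(segment_windows(rec), nfft = nfft)
  bp <- relative_band_power(spectra)
  dfs <- dominant_frequency_stats(spectra)
  per_channel <- dplyr::left_join(bp, dfs, by = "channel")
  out <- region_aggregate(per_channel, montage)
  out$TAR <- theta_alpha_ratio(out$theta, out$high_theta, out$alpha,
    numerator = tar_numerator
  )
  out
}

# one wide row of {condition}_{region}_{feature} columns from a region table
.widen_condition <- function(region_tab, condition) {
  long <- tidyr::pivot_longer(region_tab, -"region",
    names_to = "feature", values_to = "value"
  )
  long$name <- paste(condition, long$region, long$feature, sep = "_")
  tibble::as_tibble(as.list(setNames(long$value, long$name)))
}

#' Build the subjects-by-features qEEG table
#'
#' One row per subject with columns named `{EC|EO}_{F|C|T|P|O}_{feature}`
#' for the five relative band powers, DF, DFV and TAR, plus
#' `{region}_DFV_ECEO_ratio` reactivity columns for subjects with both
#' conditions. Missing conditions leave their columns `NA`.
#'
#' @param cohort Tibble with columns `subject_id`, `group` and list-columns
#'   `ec`, `eo` of [eeg_recording()] objects (as from [make_cohort()]);
#'   either list-column may contain `NULL` entries.
#' @param montage Montage used for region aggregation.
#' @param clinical Optional data frame of clinical scores with a
#'   `subject_id` column to join on (e.g. a CAMCOG memory score).
#' @param ... Passed to [recording_features()].
#' @return A `qeeg_features` tibble: `subject_id`, `group`, feature columns.
#' @export
build_feature_table <- function(cohort, montage, clinical = NULL, ...) {
  if (anyDuplicated(cohort$subject_id)) abort("duplicate subject ids")
  rows <- purrr::pmap(
    list(cohort$subject_id, cohort$group, cohort$ec, cohort$eo),
    function(sid, grp, ec, eo, ...) {
      parts <- list(tibble::tibble(subject_id = sid, group = grp))
      ec_tab <- if (!is.null(ec)) recording_features(ec, montage, ...)
      eo_tab <- if (!is.null(eo)) recording_features(eo, montage, ...)
      if (!is.null(ec_tab)) parts <- c(parts, list(.widen_condition(ec_tab, "EC")))
      if (!is.null(eo_tab)) parts <- c(parts, list(.widen_condition(eo_tab, "EO")))
      if (!is.null(ec_tab) && !is.null(eo_tab)) {
        ratio <- dfv_ec_eo_ratio(ec_tab$DFV, eo_tab$DFV)
        names(ratio) <- paste0(ec_tab$region, "_DFV_ECEO_ratio")
        parts <- c(parts, list(tibble::as_tibble(as.list(ratio))))
      }
      dplyr::bind_cols(parts)
    },
    ...
  )
  out <- dplyr::bind_rows(rows)
  if (!is.null(clinical)) {
    extra <- setdiff(names(clinical), "subject_id")
    out <- dplyr::left_join(out, clinical, by = "subject_id")
    if (!all(vapply(out[extra], is.numeric, logical(1)))) {
      warn("non-numeric clinical columns joined; classifiers expect numeric features")
    }
  }
  class(out) <- c("qeeg_features", class(out))
  out
}

#' Names of the feature columns in a feature table
#'
#' @param features A `qeeg_features` tibble.
#' @param conditions Restrict to conditions, e.g. `"EC"`; ratio columns are
#'   included only when both conditions are requested.
#' @return Character vector of column names.
#' @export
feature_columns <- function(features, conditions = c("EC", "EO")) {
  cols <- setdiff(names(features), c("subject_id", "group"))
  keep <- logical(length(cols))
  if ("EC" %in% conditions) keep <- keep | startsWith(cols, "EC_")
  if ("EO" %in% conditions) keep <- keep | startsWith(cols, "EO_")
  if (all(c("EC", "EO") %in% conditions)) {
    keep <- keep | grepl("_DFV_ECEO_ratio$", cols)
  }
  cols[keep]
}

#' Write or read a feature table as TSV
#' @param features A `qeeg_features` tibble.
#' @param path File path.
#' @export
write_feature_table <- function(features, path) {
  readr::write_tsv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("qeeg_features", class(out))
  out
}
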