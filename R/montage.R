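#' Cortical region from a 10-5 electrode label
#'
#' Maps extended 10-20 ("10-5") electrode labels onto the five cortical
#' regions used for feature aggregation: frontal (F), central (C),
#' temporal (T), parietal (P) and occipital (O). Two-letter site prefixes
#' are resolved before single letters, so `FC5` is central while `F5` is
#' frontal; midline `z` sites follow the same prefix rule.
#'
#' @param label Character vector of electrode labels (e.g. `"PO3"`, `"Cz"`).
#' @return Character vector of region codes (`"F"`, `"C"`, `"T"`, `"P"`, `"O"`),
#'   `NA` for labels with no recognised prefix.
#' @examples
#' region_from_label(c("Fp1", "FC5", "TP7", "POz", "Cz"))
#' @export
region_from_label <- function(label) {
  stem <- toupper(sub("([0-9]+|Z)$", "", label, ignore.case = TRUE))
  two <- c(FP = "F", AF = "F", FC = "C", FT = "T", TP = "T", CP = "P", PO = "O")
  one <- c(F = "F", C = "C", T = "T", P = "P", O = "O")
  out <- unname(two[substr(stem, 1, 2)])
  miss <- is.na(out)
  out[miss] <- unname(one[substr(stem[miss], 1, 1)])
  out
}

# inclination from vertex / azimuth from right preauricular axis, degrees;
# approximate spherical-head 10-5 placements, sufficient for region weighting
# and spherical-spline geometry
.montage_angles <- function() {
  tibble::tribble(
    ~label, ~theta, ~phi,
    "Fp1", 90, 108, "Fp2", 90, 72,
    "AF3", 74, 113, "AF4", 74, 67,
    "F3", 60, 128, "F4", 60, 52,
    "F7", 90, 144, "F8", 90, 36,
    "Fz", 45, 90,
    "FC1", 31, 121, "FC2", 31, 59,
    "FC5", 62, 150, "FC6", 62, 30,
    "C3", 45, 180, "C4", 45, 0, "Cz", 0, 0,
    "FT7", 90, 162, "FT8", 90, 18,
    "T7", 90, 180, "T8", 90, 0,
    "TP7", 90, 198, "TP8", 90, 342,
    "CP1", 31, 239, "CP2", 31, 301,
    "P3", 60, 232, "P4", 60, 308,
    "P7", 90, 216, "P8", 90, 324,
    "Pz", 45, 270,
    "PO3", 74, 247, "PO4", 74, 293, "POz", 68, 270,
    "O1", 90, 252, "O2", 90, 288, "Oz", 90, 270
  )
}

#' Electrode montage with unit-sphere positions and region map
#'
#' Returns the packaged montage: one row per electrode with unit-sphere
#' coordinates (x right, y anterior, z superior) and the cortical region each
#' electrode contributes to. The `"full"` layout has 35 extended 10-20 sites;
#' `"reduced"` keeps two electrodes per region (F3/F4, C3/C4, T7/T8, P3/P4,
#' O1/O2), which is the layout the packaged simulation experiments use.
#'
#' @param layout `"full"` or `"reduced"`.
#' @return A tibble with columns `label`, `x`, `y`, `z`, `region`.
#' @seealso [read_montage()] to load a custom montage from TSV.
#' @export
default_montage <- function(layout = c("full", "reduced")) {
  layout <- match.arg(layout)
  ang <- .montage_angles()
  th <- ang$theta * pi / 180
  ph <- ang$phi * pi / 180
  m <- tibble::tibble(
    label = ang$label,
    x = sin(th) * cos(ph),
    y = sin(th) * sin(ph),
    z = cos(th),
    region = region_from_label(ang$label)
  )
  if (layout == "reduced") {
    keep <- c("F3", "F4", "C3", "C4", "T7", "T8", "P3", "P4", "O1", "O2")
    m <- m[match(keep, m$label), ]
  }
  validate_montage(m)
}

#' @rdname default_montage
#' @param montage A montage data frame to validate.
#' @export
validate_montage <- function(montage) {
  req <- c("label", "x", "y", "z", "region")
  if (!all(req %in% names(montage))) {
    abort(paste("montage must have columns:", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(montage$label)) abort("duplicate electrode labels in montage")
  nrm <- sqrt(montage$x^2 + montage$y^2 + montage$z^2)
  if (any(abs(nrm - 1) > 1e-9)) abort("montage positions must lie on the unit sphere")
  if (!all(montage$region %in% c("F", "C", "T", "P", "O"))) {
    abort("montage regions must be one of F, C, T, P, O")
  }
  tibble::as_tibble(montage)
}

#' Read or write a montage TSV (label, x, y, z, region)
#'
#' @param path File path.
#' @return `read_montage()` returns a validated montage tibble.
#' @export
read_montage <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_montage(m)
}

#' @rdname read_montage
#' @param montage Montage tibble.
#' @export
write_montage <- function(montage, path) {
  montage <- validate_montage(montage)
  readr::write_tsv(montage, path, progress = FALSE)
  invisible(path)
}

# positions matrix for a set of labels, case-insensitive match
montage_positions <- function(montage, labels) {
  idx <- match(toupper(labels), toupper(montage$label))
  if (anyNA(idx)) {
    abort(paste("labels missing from montage:", paste(labels[is.na(idx)], collapse = ", ")))
  }
  pos <- as.matrix(montage[idx, c("x", "y", "z")])
  rownames(pos) <- labels
  pos
}

montage_regions <- function(montage, labels) {
  idx <- match(toupper(labels), toupper(montage$label))
  if (anyNA(idx)) {
    abort(paste("labels missing from montage:", paste(labels[is.na(idx)], collapse = ", ")))
  }
  setNames(montage$region[idx], labels)
}
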