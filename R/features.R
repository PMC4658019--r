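#' Assemble the 256-feature vector for one ROI
#'
#' For each of the eight contrasts: raw mean and SD of the unscaled
#' intensities, then 13 GLCM, 12 LBP and 5 DOST texture features computed
#' per contrast independently (30 texture features per contrast, 240
#' texture + 16 raw = 256 features total).
#'
#' @param patches Named list of `roi_patch`, one per contrast in
#'   [contrast_names()].
#' @param glcm_levels Gray levels for GLCM quantization.
#' @return Named numeric vector of length 256 ordered per
#'   [feature_registry()].
#' @export
assemble_feature_vector <- function(patches, glcm_levels = 16L) {
  missing <- setdiff(contrast_names(), names(patches))
  if (length(missing))
    stop("missing contrast(s): ", paste(missing, collapse = ", "))
  out <- unlist(lapply(contrast_names(), function(cn) {
    p <- patches[[cn]]
    c(first_order_stats(p),
      compute_glcm_features(p, glcm_levels),
      compute_lbp_features(p),
      compute_dost_features(p))
  }), use.names = FALSE)
  names(out) <- feature_registry()
  if (!all(is.finite(out)))
    stop("non-finite feature value(s): ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Extract the feature table for a set of biopsy sites
#'
#' Runs ROI extraction and all three texture algorithms over every site of
#' every patient, producing one row per site with the 256 named feature
#' columns plus site metadata (patient, location, zone, percent tumor
#' nuclei, label).
#'
#' @param volumes Named list: per patient id, a named list of the eight
#'   `contrast_volume`s.
#' @param sites List of `biopsy_site`s.
#' @inheritParams assemble_feature_vector
#' @return `data.frame` with metadata columns then 256 feature columns.
#' @export
extract_features <- function(volumes, sites, glcm_levels = 16L) {
  rows <- lapply(sites, function(s) {
    vols <- volumes[[s$patient_id]]
    if (is.null(vols)) stop("no volumes for patient ", s$patient_id)
    patches <- lapply(vols[contrast_names()], extract_roi, site = s)
    assemble_feature_vector(patches, glcm_levels)
  })
  feats <- do.call(rbind, rows)
  meta <- data.frame(
    patient_id = vapply(sites, `[[`, "", "patient_id"),
    slice = vapply(sites, `[[`, 0L, "slice"),
    row0 = vapply(sites, `[[`, 0L, "row0"),
    col0 = vapply(sites, `[[`, 0L, "col0"),
    zone = vapply(sites, `[[`, "", "zone"),
    pct_tumor_nuclei = vapply(sites, `[[`, 0, "pct_tumor_nuclei"),
    label = vapply(sites, `[[`, "", "label"),
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(feats, check.names = FALSE))
}

feature_columns <- function(df) {
  df[, feature_registry(), drop = FALSE]
}

#' Write / read a feature table CSV
#'
#' One row per (patient, site); metadata columns then the 256 named
#' feature columns.
#'
#' @param features Feature `data.frame` from [extract_features()].
#' @param path CSV path.
#' @return The path (write) or the `data.frame` (read).
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(feature_registry(), names(df))
  if (length(missing))
    stop("feature table missing ", length(missing), " column(s), e.g. ",
         missing[1])
  df
}
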