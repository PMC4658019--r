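#' Construct a contrast volume
#'
#' A coregistered 3D intensity map for one named MRI contrast. All eight
#' contrasts of a patient must share the same grid (coregistration
#' contract); this is checked where volumes are consumed together.
#'
#' @param name Contrast name, one of [contrast_names()].
#' @param data 3D numeric array indexed (slice, row, col).
#' @param voxel_size_mm Numeric length-3 `(dz, dy, dx)` voxel size in mm.
#' @return An object of class `contrast_volume`.
#' @export
contrast_volume <- function(name, data, voxel_size_mm = c(3, 1.2, 1.2)) {
  if (!name %in% contrast_names())
    stop("unknown contrast name: ", name)
  if (length(dim(data)) != 3L)
    stop("contrast volume data must be a 3D array")
  if (!all(is.finite(data)))
    stop("contrast volume contains non-finite values")
  structure(list(name = name, data = data,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "contrast_volume")
}

#' @export
print.contrast_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<contrast_volume %s: %d x %d x %d voxels, %.1f x %.2f x %.2f mm>\n",
              x$name, d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' Write a contrast volume as NIfTI
#'
#' One file per contrast per patient, named `<patient>_<contrast>.nii.gz`
#' when written through [write_cohort()]. `+` in contrast names is kept
#' as-is in filenames.
#'
#' @param vol A `contrast_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  # NIfTI stores (x, y, z); our arrays are (slice, row, col) so permute.
  arr <- aperm(vol$data, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(vol$voxel_size_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a contrast volume from NIfTI
#'
#' @param path NIfTI file path.
#' @param name Contrast name to attach; by default parsed from the filename
#'   tail `<patient>_<contrast>.nii(.gz)`.
#' @return A `contrast_volume`.
#' @export
read_volume <- function(path, name = NULL) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("malformed volume (expected 3D image): ", path)
  if (is.null(name)) {
    base <- sub("\\.nii(\\.gz)?$", "", basename(path))
    name <- sub("^.*_", "", base)
  }
  pd <- RNifti::pixdim(img)
  contrast_volume(name, aperm(as.array(img), c(3, 2, 1)),
                  voxel_size_mm = rev(pd[1:3]))
}

roi_size <- 8L

#' Construct a biopsy site
#'
#' Location, zone and histologic label for one tissue sample. Coordinates
#' are 0-based voxel indices of the ROI's top-left corner; the ROI spans
#' rows `[row0, row0 + 8)` and columns `[col0, col0 + 8)` (half-open) on
#' the stated slice. The class label is `high` iff the percent tumor
#' nuclei is at least 80 (TCGA sample-adequacy threshold).
#'
#' @param patient_id Patient identifier.
#' @param slice,row0,col0 0-based voxel indices.
#' @param zone `"ENH"` (enhancing core) or `"BAT"` (brain-around-tumor).
#' @param pct_tumor_nuclei Percent tumor nuclei in `[0, 100]`.
#' @return An object of class `biopsy_site`.
#' @export
biopsy_site <- function(patient_id, slice, row0, col0, zone,
                        pct_tumor_nuclei) {
  zone <- match.arg(zone, c("ENH", "BAT"))
  if (pct_tumor_nuclei < 0 || pct_tumor_nuclei > 100)
    stop("pct_tumor_nuclei must lie in [0, 100]")
  structure(list(patient_id = as.character(patient_id),
                 slice = as.integer(slice), row0 = as.integer(row0),
                 col0 = as.integer(col0), zone = zone,
                 pct_tumor_nuclei = as.numeric(pct_tumor_nuclei),
                 label = if (pct_tumor_nuclei >= 80) "high" else "low"),
            class = "biopsy_site")
}

site_table_columns <- c("patient_id", "slice", "row0", "col0", "zone",
                        "pct_tumor_nuclei")

#' Write a biopsy-site table as CSV
#'
#' @param sites List of `biopsy_site` objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_sites <- function(sites, path) {
  df <- do.call(rbind, lapply(sites, function(s)
    data.frame(patient_id = s$patient_id, slice = s$slice, row0 = s$row0,
               col0 = s$col0, zone = s$zone,
               pct_tumor_nuclei = s$pct_tumor_nuclei,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a biopsy-site table from CSV
#'
#' Expects columns `patient_id, slice, row0, col0, zone, pct_tumor_nuclei`
#' (0-based voxel indices, half-open 8x8 ROI). Labels are derived from
#' percent tumor nuclei at the 80% threshold, never stored.
#'
#' @param path CSV path.
#' @return List of `biopsy_site` objects.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(site_table_columns, names(df))
  if (length(missing))
    stop("site table missing column(s): ", paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    biopsy_site(df$patient_id[i], df$slice[i], df$row0[i], df$col0[i],
                df$zone[i], df$pct_tumor_nuclei[i]))
}

#' Extract an 8x8 ROI patch from a contrast volume
#'
#' Returns both the raw 8x8 sub-grid at the site's footprint and its
#' rescaled version: an affine map of raw onto `[0, 255]` (min to 0, max
#' to 255) with floor rounding to integers. A constant patch maps to all
#' zeros. Rescaling standardizes intensities between ROIs prior to texture
#' analysis and is invariant to positive affine transforms of the raw
#' intensities.
#'
#' @param volume A `contrast_volume`.
#' @param site A `biopsy_site` (or any list with `slice`, `row0`, `col0`).
#' @return An object of class `roi_patch` with fields `contrast_name`,
#'   `raw` and `rescaled` (both 8x8 matrices).
#' @export
extract_roi <- function(volume, site) {
  d <- dim(volume$data)
  sl <- site$slice; r0 <- site$row0; c0 <- site$col0
  if (sl < 0 || sl >= d[1] || r0 < 0 || c0 < 0 ||
      r0 + roi_size > d[2] || c0 + roi_size > d[3])
    stop(sprintf(
      "ROI out of bounds: slice %d rows [%d,%d) cols [%d,%d) in %d x %d x %d volume",
      sl, r0, r0 + roi_size, c0, c0 + roi_size, d[1], d[2], d[3]))
  raw <- volume$data[sl + 1L, (r0 + 1L):(r0 + roi_size),
                     (c0 + 1L):(c0 + roi_size)]
  roi_patch(volume$name, raw)
}

#' @rdname extract_roi
#' @param contrast_name Contrast the patch came from.
#' @param raw 8x8 numeric matrix of raw intensities.
#' @export
roi_patch <- function(contrast_name, raw) {
  raw <- as.matrix(raw)
  if (!all(dim(raw) == roi_size)) stop("ROI patch must be 8x8")
  structure(list(contrast_name = contrast_name, raw = raw,
                 rescaled = rescale_255(raw)),
            class = "roi_patch")
}

# Affine map onto [0,255] with floor rounding; constant patch -> all zeros.
# Max maps to 255 exactly (floor is applied to values strictly below the
# top of each unit cell; the max itself hits 255).
rescale_255 <- function(raw) {
  rng <- range(raw)
  if (rng[1] == rng[2]) return(matrix(0L, roi_size, roi_size))
  sc <- floor((raw - rng[1]) / (rng[2] - rng[1]) * 255)
  storage.mode(sc) <- "integer"
  sc
}

#' First-order statistics of an ROI
#'
#' Mean and standard deviation of the raw (pre-rescaling) intensities.
#' The SD uses the population denominator n = 64: it is a descriptive
#' statistic over a fixed window, not an estimate from a sample.
#'
#' @param patch An `roi_patch`.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
first_order_stats <- function(patch) {
  x <- patch$raw
  m <- mean(x)
  c(mean = m, sd = sqrt(mean((x - m)^2)))
}
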