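#' Render a tumor-probability map for one slice
#'
#' Slides an 8x8 window at the given stride over all valid positions of
#' the slice and runs the identical chain used for biopsy ROIs (patch
#' extraction, rescaling, texture features, training-fitted reduction,
#' classifier posterior). The posterior probability of high-tumor content
#' is assigned at the window center; positions outside the evaluable mask
#' are `NA`. Stride 1 gives the densest map.
#'
#' @param volumes Named list of the eight `contrast_volume`s of one
#'   patient.
#' @param model A [tumor_content_model()].
#' @param slice 0-based slice index.
#' @param stride Window stride in voxels.
#' @param glcm_levels GLCM quantization levels (must match training).
#' @return Object of class `tumor_probability_map`: `prob` (2D grid of
#'   posteriors, `NA` outside the mask), `mask`, `slice`, `stride`.
#' @export
render_probability_map <- function(volumes, model, slice, stride = 4L,
                                   glcm_levels = 16L) {
  missing <- setdiff(contrast_names(), names(volumes))
  if (length(missing))
    stop("missing contrast(s): ", paste(missing, collapse = ", "))
  d <- dim(volumes[[1]]$data)
  if (slice < 0 || slice >= d[1]) stop("slice out of bounds")
  r0s <- seq(0L, d[2] - roi_size, by = stride)
  c0s <- seq(0L, d[3] - roi_size, by = stride)
  grid <- expand.grid(row0 = r0s, col0 = c0s)
  feats <- t(vapply(seq_len(nrow(grid)), function(i) {
    site <- list(slice = slice, row0 = grid$row0[i], col0 = grid$col0[i])
    patches <- lapply(volumes[contrast_names()], extract_roi, site = site)
    assemble_feature_vector(patches, glcm_levels)
  }, numeric(256)))
  feats <- as.data.frame(feats, check.names = FALSE)
  p <- stats::predict(model, feats)$p_high
  prob <- matrix(NA_real_, d[2], d[3])
  mask <- matrix(FALSE, d[2], d[3])
  ctr <- cbind(grid$row0 + roi_size %/% 2 + 1L,
               grid$col0 + roi_size %/% 2 + 1L)
  prob[ctr] <- p
  mask[ctr] <- TRUE
  structure(list(prob = prob, mask = mask, slice = slice,
                 stride = stride), class = "tumor_probability_map")
}

#' @export
print.tumor_probability_map <- function(x, ...) {
  cat(sprintf("<tumor_probability_map: slice %d, stride %d, %d centers, mean p %.3f>\n",
              x$slice, x$stride, sum(x$mask),
              mean(x$prob[x$mask])))
  invisible(x)
}

#' Write a probability map as NIfTI (float)
#'
#' @param map A `tumor_probability_map`.
#' @param path Output NIfTI path.
#' @param voxel_size_mm `(dz, dy, dx)`.
#' @return `path`, invisibly.
#' @export
write_probability_map <- function(map, path,
                                  voxel_size_mm = c(3, 1.2, 1.2)) {
  arr <- array(t(map$prob), dim = c(ncol(map$prob), nrow(map$prob), 1))
  img <- RNifti::asNifti(arr, pixdim = rev(voxel_size_mm))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Plot a probability map as a colour overlay
#'
#' Blue-to-red colormap over `[0, 1]` alpha-blended onto the T2W slice,
#' the usual presentation of such maps. Purely presentational.
#'
#' @param x A `tumor_probability_map`.
#' @param t2w Optional `contrast_volume` supplying the anatomical
#'   background.
#' @param ... Unused.
#' @export
plot.tumor_probability_map <- function(x, t2w = NULL, ...) {
  if (!is.null(t2w)) {
    bg <- t2w$data[x$slice + 1L, , ]
    bg <- (bg - min(bg)) / max(diff(range(bg)), 1e-12)
    graphics::image(seq_len(nrow(bg)), seq_len(ncol(bg)), bg,
                    col = grDevices::gray.colors(64), xlab = "row",
                    ylab = "col", useRaster = TRUE)
    graphics::image(seq_len(nrow(x$prob)), seq_len(ncol(x$prob)), x$prob,
                    col = grDevices::adjustcolor(
                      grDevices::hcl.colors(64, "Blue-Red"), alpha.f = 0.6),
                    add = TRUE, useRaster = TRUE, zlim = c(0, 1))
  } else {
    graphics::image(seq_len(nrow(x$prob)), seq_len(ncol(x$prob)), x$prob,
                    col = grDevices::hcl.colors(64, "Blue-Red"),
                    xlab = "row", ylab = "col", zlim = c(0, 1),
                    useRaster = TRUE)
  }
  invisible(x)
}
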