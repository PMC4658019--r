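#' Canonical MRI contrast names
#'
#' The eight coregistered contrasts the classifier consumes, in the fixed
#' order used throughout the package: post-contrast T1 (T1+C), T2-weighted
#' (T2W), relative cerebral blood volume (rCBV), post-contrast echo-planar
#' T2* (EPI+C), isotropic (p) and anisotropic (q) diffusion, mean
#' diffusivity (MD) and fractional anisotropy (FA).
#'
#' @return Character vector of length 8.
#' @export
contrast_names <- function() {
  c("T1+C", "T2W", "rCBV", "EPI+C", "p", "q", "MD", "FA")
}

# Per-contrast feature names within each algorithm block.
glcm_feature_names <- function() {
  c("energy", "entropy", "homogeneity", "dissimilarity", "correlation",
    "contrast", "variance", "sum_average", "sum_variance", "sum_entropy",
    "diff_variance", "diff_entropy", "imc1")
}

lbp_feature_names <- function() sprintf("bin%02d", 1:12)

dost_feature_names <- function() {
  c("dc", "band1", "band2", "band3", "spectral_entropy")
}

#' Feature-name registry
#'
#' The 256 image-based feature names (16 raw + 240 texture) in their fixed
#' ordering: for each contrast, raw mean and SD, then 13 GLCM, 12 LBP and
#' 5 DOST features. Column names follow `<contrast>__<algorithm>__<feature>`.
#'
#' @return Character vector of length 256.
#' @export
feature_registry <- function() {
  unlist(lapply(contrast_names(), function(cn) {
    c(paste0(cn, "__RAW__", c("mean", "sd")),
      paste0(cn, "__GLCM__", glcm_feature_names()),
      paste0(cn, "__LBP__", lbp_feature_names()),
      paste0(cn, "__DOST__", dost_feature_names()))
  }), use.names = FALSE)
}

#' Write the feature registry as JSON
#'
#' Exports the feature naming scheme (contrast, algorithm, feature, column
#' name) for downstream interpretability of selected features.
#'
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_feature_registry <- function(path) {
  nm <- feature_registry()
  parts <- do.call(rbind, strsplit(nm, "__", fixed = TRUE))
  reg <- data.frame(column = nm, contrast = parts[, 1],
                    algorithm = parts[, 2], feature = parts[, 3],
                    stringsAsFactors = FALSE)
  jsonlite::write_json(reg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Block structure: 24 texture blocks + 8 raw blocks covering all 256
# features exactly once. Returns a data.frame with contrast, algorithm.
feature_blocks <- function() {
  expand.grid(contrast = contrast_names(),
              algorithm = c("RAW", "GLCM", "LBP", "DOST"),
              stringsAsFactors = FALSE)
}

block_columns <- function(contrast, algorithm) {
  feats <- switch(algorithm,
                  RAW  = c("mean", "sd"),
                  GLCM = glcm_feature_names(),
                  LBP  = lbp_feature_names(),
                  DOST = dost_feature_names(),
                  stop("unknown algorithm block: ", algorithm))
  paste0(contrast, "__", algorithm, "__", feats)
}
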