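#' Fit the block-wise principal component reduction
#'
#' Features are reduced separately for each (contrast x texture algorithm)
#' block so the retained components stay clinically interpretable. Each of
#' the 24 texture blocks is z-scored with training statistics (zero-
#' variance columns get unit scale and contribute nothing) and
#' eigendecomposed; the smallest number of components whose cumulative
#' explained variance reaches 85% is retained. The raw mean/SD features
#' bypass component combination: each is standardized and passed through
#' as its own feature, so a selected "rCBV raw mean" remains directly
#' readable. Loading signs are fixed so each component's largest-magnitude
#' entry is positive.
#'
#' @param training_features Feature `data.frame` (rows = samples) holding
#'   the 256 registry columns; extra metadata columns are ignored.
#' @param var_explained Retained cumulative variance fraction (default
#'   0.85).
#' @param fixed_k Optional named list/vector (block id
#'   `<contrast>__<algorithm>` to component count) overriding the variance
#'   rule; used when the reduction is refitted inside cross-validation
#'   folds with the component count held fixed.
#' @return Object of class `pc_reduction`: per-block models plus the
#'   output column names.
#' @export
fit_reduction <- function(training_features, var_explained = 0.85,
                          fixed_k = NULL) {
  x <- as.matrix(feature_columns(training_features))
  if (nrow(x) < 3) stop("need at least 3 samples to fit the reduction")
  if (anyNA(x)) stop("missing values in training features")
  blocks <- feature_blocks()
  models <- list()
  for (b in seq_len(nrow(blocks))) {
    cn <- blocks$contrast[b]; alg <- blocks$algorithm[b]
    cols <- block_columns(cn, alg)
    xb <- x[, cols, drop = FALSE]
    mu <- colMeans(xb)
    sc <- apply(xb, 2, stats::sd)
    sc[sc == 0] <- 1
    z <- sweep(sweep(xb, 2, mu), 2, sc, "/")
    id <- paste0(cn, "__", alg)
    if (alg == "RAW") {
      models[[id]] <- list(contrast = cn, algorithm = alg, columns = cols,
                           means = mu, scales = sc, passthrough = TRUE,
                           out_names = paste0(cn, "__raw_",
                                              c("mean", "sd")))
      next
    }
    eg <- eigen(stats::cov(z), symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    total <- sum(ev)
    cumfrac <- if (total > 0) cumsum(ev) / total else rep(1, length(ev))
    k <- if (!is.null(fixed_k) && !is.null(fixed_k[[id]]))
      as.integer(fixed_k[[id]]) else which(cumfrac >= var_explained)[1]
    load <- eg$vectors[, seq_len(k), drop = FALSE]
    # sign convention: largest-magnitude entry of each loading positive
    for (j in seq_len(k)) {
      i <- which.max(abs(load[, j]))
      if (load[i, j] < 0) load[, j] <- -load[, j]
    }
    models[[id]] <- list(contrast = cn, algorithm = alg, columns = cols,
                         means = mu, scales = sc, passthrough = FALSE,
                         loadings = load, k = k,
                         eigenvalues = ev[seq_len(k)],
                         explained = cumfrac[k],
                         out_names = paste0(cn, "__", alg, "__PC",
                                            seq_len(k)))
  }
  structure(list(models = models, var_explained = var_explained,
                 out_names = unlist(lapply(models, `[[`, "out_names"),
                                    use.names = FALSE)),
            class = "pc_reduction")
}

#' @export
print.pc_reduction <- function(x, ...) {
  ks <- vapply(x$models, function(m)
    if (m$passthrough) length(m$columns) else m$k, 0L)
  cat(sprintf("<pc_reduction: %d blocks -> %d features (%d%% variance rule)>\n",
              length(x$models), sum(ks), round(100 * x$var_explained)))
  invisible(x)
}

#' Apply a fitted reduction to a feature table
#'
#' Validation data are transformed with the stored training means, scales
#' and loadings only; nothing is refitted.
#'
#' @param reduction A `pc_reduction`.
#' @param features Feature `data.frame` with the 256 registry columns.
#' @return `data.frame` of reduced features with columns
#'   `<contrast>__<algorithm>__PC<i>` and `<contrast>__raw_mean` /
#'   `<contrast>__raw_sd`.
#' @export
transform_features <- function(reduction, features) {
  missing <- setdiff(feature_registry(), names(features))
  if (length(missing))
    stop("feature column(s) missing from input: ", missing[1],
         if (length(missing) > 1) sprintf(" (+%d more)", length(missing) - 1))
  x <- as.matrix(feature_columns(features))
  out <- lapply(reduction$models, function(m) {
    z <- sweep(sweep(x[, m$columns, drop = FALSE], 2, m$means),
               2, m$scales, "/")
    if (m$passthrough) z else z %*% m$loadings
  })
  out <- do.call(cbind, out)
  colnames(out) <- reduction$out_names
  as.data.frame(out, check.names = FALSE)
}

#' Serialize / restore a fitted reduction as JSON
#'
#' @param reduction A `pc_reduction`.
#' @param path JSON path.
#' @return `path` (write) or the restored `pc_reduction` (read).
#' @export
write_reduction <- function(reduction, path) {
  ser <- lapply(reduction$models, function(m) {
    m$loadings <- if (!is.null(m$loadings)) unclass(m$loadings)
    m
  })
  jsonlite::write_json(list(var_explained = reduction$var_explained,
                            models = ser),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reduction
#' @export
read_reduction <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(obj$models, function(m) {
    if (!is.null(m$loadings))
      m$loadings <- matrix(unlist(m$loadings), ncol = m$k)
    m$means <- stats::setNames(as.numeric(m$means), m$columns)
    m$scales <- stats::setNames(as.numeric(m$scales), m$columns)
    m
  })
  structure(list(models = models, var_explained = obj$var_explained,
                 out_names = unlist(lapply(models, `[[`, "out_names"),
                                    use.names = FALSE)),
            class = "pc_reduction")
}
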