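#' Fit the tumor-content classification model
#'
#' The full modelling chain on a training feature table: block-wise
#' principal component reduction at the 85% variance rule (raw mean/SD
#' pass through as their own features), sequential forward feature
#' selection over the reduced pool under leave-one-out cross-validation
#' with the <1 accuracy point stopping rule, and a final classifier
#' (DLDA by default) fitted on the selected features.
#'
#' By default the reduction is fitted once on the full training set, with
#' only the classifier nested in the LOOCV loop; `pca_in_folds = TRUE`
#' refits the reduction inside every fold (holding each block's component
#' count fixed) as a sensitivity analysis for the small leakage the
#' one-shot fit admits.
#'
#' @param features Training feature `data.frame` from [extract_features()]
#'   (or [read_features()]): metadata plus the 256 registry columns.
#' @param labels Optional label vector `"high"`/`"low"`; defaults to the
#'   `label` column of `features`.
#' @param classifier `"dlda"`, `"dqda"` or `"svm"`.
#' @param gain_threshold Forward-selection stopping threshold in accuracy
#'   points (default 0.01).
#' @param var_explained PCA retained-variance rule (default 0.85).
#' @param pca_in_folds Refit the reduction inside each LOOCV fold.
#' @param C SVM cost.
#' @return Object of class `tumor_content_model`.
#' @export
tumor_content_model <- function(features, labels = features$label,
                                classifier = c("dlda", "dqda", "svm"),
                                gain_threshold = 0.01,
                                var_explained = 0.85,
                                pca_in_folds = FALSE, C = 1) {
  classifier <- match.arg(classifier)
  if (is.null(labels)) stop("no labels supplied and no 'label' column")
  labels <- as.character(labels)
  reduction <- fit_reduction(features, var_explained)
  reduced <- transform_features(reduction, features)

  if (!pca_in_folds) {
    trace <- forward_select(reduced, labels, classifier, gain_threshold,
                            C = C)
  } else {
    trace <- forward_select_infold(features, labels, reduction,
                                   classifier, gain_threshold,
                                   var_explained, C)
  }
  sel <- trace$selected
  if (length(sel) == 0)
    warning("no feature cleared the gain threshold; ",
            "model falls back to the single best candidate")
  if (length(sel) == 0) sel <- best_single_feature(reduced, labels,
                                                   classifier, C)
  final <- fit_classifier(reduced[, sel, drop = FALSE], labels,
                          classifier, C = C)
  structure(list(classifier = classifier, reduction = reduction,
                 trace = trace, selected = sel, fit = final,
                 cv_accuracy = if (length(trace$cv_accuracy))
                   trace$cv_accuracy[length(trace$cv_accuracy)]
                 else trace$baseline,
                 n_train = nrow(features),
                 class_counts = table(factor(labels, classes)),
                 gain_threshold = gain_threshold,
                 var_explained = var_explained,
                 pca_in_folds = pca_in_folds, C = C,
                 call = match.call()),
            class = "tumor_content_model")
}

best_single_feature <- function(reduced, labels, classifier, C) {
  acc <- vapply(colnames(reduced), function(f)
    loocv_accuracy(reduced[, f, drop = FALSE], labels, classifier, C = C),
    numeric(1))
  names(acc)[which.max(acc)]
}

# Forward selection where every LOOCV fold refits the reduction on its
# n-1 training samples (component counts per block held at the full-fit
# values so candidate names stay stable across folds).
forward_select_infold <- function(features, labels, full_reduction,
                                  classifier, gain_threshold,
                                  var_explained, C) {
  ks <- lapply(full_reduction$models, function(m)
    if (m$passthrough) NULL else m$k)
  ks <- ks[!vapply(ks, is.null, TRUE)]
  n <- nrow(features)
  fold_frames <- lapply(seq_len(n), function(i) {
    red <- fit_reduction(features[-i, , drop = FALSE], var_explained,
                         fixed_k = ks)
    list(train = transform_features(red, features[-i, , drop = FALSE]),
         test = transform_features(red, features[i, , drop = FALSE]))
  })
  loocv_fold <- function(cols) {
    correct <- 0L
    for (i in seq_len(n)) {
      ytr <- labels[-i]
      pred <- if (length(unique(ytr)) < 2) ytr[1] else
        fit_predict_one(fold_frames[[i]]$train[, cols, drop = FALSE],
                        ytr,
                        fold_frames[[i]]$test[, cols, drop = FALSE],
                        classifier, C)
      if (pred == labels[i]) correct <- correct + 1L
    }
    correct / n
  }
  candidates <- full_reduction$out_names
  selected <- character(0); accs <- numeric(0)
  current <- max(table(labels)) / n
  baseline <- current; stop_reason <- "exhausted"
  while (length(selected) < length(candidates)) {
    remaining <- setdiff(candidates, selected)
    trial <- vapply(remaining, function(f) loocv_fold(c(selected, f)),
                    numeric(1))
    if (max(trial) - current < gain_threshold) {
      stop_reason <- "gain<threshold"; break
    }
    selected <- c(selected, remaining[which.max(trial)])
    current <- max(trial)
    accs <- c(accs, current)
  }
  structure(list(selected = selected, cv_accuracy = accs,
                 baseline = baseline, stop_reason = stop_reason,
                 gain_threshold = gain_threshold, classifier = classifier),
            class = "selection_trace")
}

#' @export
print.tumor_content_model <- function(x, ...) {
  cat("Tumor-content classification model (", toupper(x$classifier),
      ")\n", sep = "")
  cat(sprintf("  training samples: %d (high %d / low %d)\n", x$n_train,
              x$class_counts["high"], x$class_counts["low"]))
  cat(sprintf("  selected features (%d): %s\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  cat(sprintf("  LOOCV accuracy: %.3f\n", x$cv_accuracy))
  invisible(x)
}

#' @export
summary.tumor_content_model <- function(object, ...) {
  cat("Call: "); print(object$call)
  print(object)
  cat("\nSelection trace:\n")
  print(object$trace)
  ks <- vapply(object$reduction$models, function(m)
    if (m$passthrough) NA_integer_ else m$k, 0L)
  ks <- ks[!is.na(ks)]
  cat(sprintf("\nReduction: %d texture blocks, retained PCs per block: %s\n",
              length(ks), paste(range(ks), collapse = "-")))
  invisible(object)
}

#' @export
coef.tumor_content_model <- function(object, ...) {
  if (!inherits(object$fit, "diag_discriminant"))
    stop("coef() is defined for the DLDA/DQDA fits")
  list(selected = object$selected, class_means = object$fit$means,
       variances = object$fit$sigma2,
       priors = exp(object$fit$log_priors))
}

#' Predict tumor content for new feature rows
#'
#' Transforms the 256-feature rows with the training-fitted reduction
#' (no refit), subsets the selected features and applies the final
#' classifier.
#'
#' @param object A `tumor_content_model`.
#' @param newdata Feature `data.frame` with the 256 registry columns.
#' @param ... Unused.
#' @return `data.frame` with `label`, `p_high`, `p_low`.
#' @export
predict.tumor_content_model <- function(object, newdata, ...) {
  reduced <- transform_features(object$reduction, newdata)
  stats::predict(object$fit, reduced[, object$selected, drop = FALSE])
}

#' Plot the forward-selection trace
#'
#' Cross-validated accuracy after each added feature, starting from the
#' majority-class baseline.
#'
#' @param x A `tumor_content_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tumor_content_model <- function(x, ...) {
  tr <- x$trace
  acc <- c(tr$baseline, tr$cv_accuracy)
  graphics::plot(seq_along(acc) - 1, acc, type = "b", pch = 19,
                 xlab = "features selected", ylab = "LOOCV accuracy",
                 ylim = c(min(acc) - 0.05, 1), ...)
  graphics::text(seq_along(acc) - 1, acc,
                 c("baseline", tr$selected), pos = 3, cex = 0.7)
  invisible(x)
}
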