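#' Leave-one-out cross-validated accuracy
#'
#' Exactly n folds: fold i trains on the other n-1 samples and predicts
#' sample i; the accuracy is the fraction of correct held-out predictions.
#' A fold whose training split contains a single class predicts that class
#' (degenerate rule; it cannot arise unless one class has a single
#' sample).
#'
#' @param x Samples x features matrix or data.frame.
#' @param y Labels `"high"` / `"low"`.
#' @param classifier `"dlda"`, `"dqda"` or `"svm"`.
#' @param C SVM cost.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
loocv_accuracy <- function(x, y, classifier = "dlda", C = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("LOOCV needs at least 3 samples")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (classifier %in% c("dlda", "dqda"))
    return(loocv_diag(x, y, classifier))
  correct <- 0L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    pred <- if (length(unique(ytr)) < 2) ytr[1] else
      fit_predict_one(x[-i, , drop = FALSE], ytr,
                      x[i, , drop = FALSE], classifier, C)
    if (pred == y[i]) correct <- correct + 1L
  }
  correct / n
}

# Closed-form leave-one-out for the diagonal discriminants: per-class
# sums and sums of squares are downdated per fold, reproducing
# fit_dlda/fit_dqda + predict on the n-1 training samples exactly
# (same denominators, variance floor and low-tie rule).
loocv_diag <- function(x, y, classifier, eps = 1e-9) {
  n <- nrow(x)
  idx <- lapply(classes, function(cl) y == cl)
  names(idx) <- classes
  ncl <- vapply(idx, sum, 0L)
  S <- lapply(idx, function(m) colSums(x[m, , drop = FALSE]))
  Q <- lapply(idx, function(m) colSums(x[m, , drop = FALSE]^2))
  correct <- 0L
  for (i in seq_len(n)) {
    ci <- y[i]
    xi <- x[i, ]
    np <- ncl; np[ci] <- np[ci] - 1L
    if (any(np == 0)) {                 # single-class training fold
      pred <- classes[np > 0][1]
      if (pred == y[i]) correct <- correct + 1L
      next
    }
    Sp <- S; Qp <- Q
    Sp[[ci]] <- Sp[[ci]] - xi
    Qp[[ci]] <- Qp[[ci]] - xi^2
    mu <- lapply(classes, function(cl) Sp[[cl]] / np[cl])
    names(mu) <- classes
    W <- lapply(classes, function(cl)
      pmax(Qp[[cl]] - Sp[[cl]]^2 / np[cl], 0))
    names(W) <- classes
    if (classifier == "dlda") {
      s2 <- pmax((W$high + W$low) / (n - 1 - 2), eps)
      s2c <- list(high = s2, low = s2)
    } else {
      s2c <- lapply(classes, function(cl)
        pmax(W[[cl]] / max(np[cl] - 1, 1), eps))
      names(s2c) <- classes
    }
    lj <- vapply(classes, function(cl)
      -0.5 * sum((xi - mu[[cl]])^2 / s2c[[cl]]) -
        0.5 * sum(log(2 * pi * s2c[[cl]])) + log(np[cl] / (n - 1)),
      numeric(1))
    pred <- if (lj["high"] > lj["low"]) "high" else "low"
    if (pred == y[i]) correct <- correct + 1L
  }
  correct / n
}

fit_predict_one <- function(xtr, ytr, xte, classifier, C) {
  model <- fit_classifier(xtr, ytr, classifier, C = C)
  stats::predict(model, xte)$label
}

#' Sequential forward feature selection
#'
#' Greedy selection over the reduced feature pool (principal components
#' plus raw pass-throughs): each round evaluates adding every unselected
#' feature by LOOCV accuracy and adds the best one if its gain over the
#' current accuracy is at least `gain_threshold` (default 0.01, i.e. one
#' accuracy point); otherwise selection stops. The starting baseline is
#' the majority-class accuracy (the 0-feature classifier). Ties are broken
#' toward the lower column index, making the trace deterministic for fixed
#' inputs.
#'
#' @param x_reduced Reduced feature `data.frame` (columns are candidates).
#' @param y Labels.
#' @param classifier `"dlda"`, `"dqda"` or `"svm"`.
#' @param gain_threshold Minimum LOOCV accuracy gain to continue.
#' @param C SVM cost.
#' @return Object of class `selection_trace`: `selected` (ordered names),
#'   `cv_accuracy` after each addition, `baseline`, `stop_reason`
#'   (`"gain<threshold"` or `"exhausted"`), `gain_threshold`.
#' @export
forward_select <- function(x_reduced, y, classifier = "dlda",
                           gain_threshold = 0.01, C = 1) {
  x <- as.matrix(x_reduced)
  if (ncol(x) < 1) stop("need at least one candidate feature")
  candidates <- colnames(x)
  selected <- character(0)
  accs <- numeric(0)
  current <- max(table(y)) / length(y)      # majority-class baseline
  baseline <- current
  stop_reason <- "exhausted"
  while (length(selected) < length(candidates)) {
    remaining <- setdiff(candidates, selected)
    trial <- vapply(remaining, function(f)
      loocv_accuracy(x[, c(selected, f), drop = FALSE], y, classifier,
                     C = C), numeric(1))
    best <- remaining[which.max(trial)]     # which.max: first = lowest index
    if (max(trial) - current < gain_threshold) {
      stop_reason <- "gain<threshold"
      break
    }
    selected <- c(selected, best)
    current <- max(trial)
    accs <- c(accs, current)
  }
  structure(list(selected = selected, cv_accuracy = accs,
                 baseline = baseline, stop_reason = stop_reason,
                 gain_threshold = gain_threshold,
                 classifier = classifier),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("Sequential forward selection (%s, LOOCV, gain >= %.3f)\n",
              x$classifier, x$gain_threshold))
  cat(sprintf("  baseline (majority class): %.3f\n", x$baseline))
  if (length(x$selected) == 0) {
    cat("  no feature cleared the gain threshold\n")
  } else {
    for (i in seq_along(x$selected))
      cat(sprintf("  %d. %-28s cv accuracy %.3f\n", i, x$selected[i],
                  x$cv_accuracy[i]))
  }
  cat("  stop reason:", x$stop_reason, "\n")
  invisible(x)
}

#' Write a selection trace as JSON
#'
#' @param trace A `selection_trace`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  jsonlite::write_json(unclass(trace), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
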