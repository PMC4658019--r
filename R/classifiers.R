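classes <- c("high", "low")

check_xy <- function(x, y) {
  x <- as.matrix(x)
  y <- factor(y, levels = classes)
  if (anyNA(y)) stop("labels must be 'high' or 'low'")
  if (length(unique(y[!is.na(y)])) < 2)
    stop("both classes must be present to fit a classifier")
  if (nrow(x) != length(y)) stop("nrow(x) must match length(y)")
  list(x = x, y = y)
}

#' Diagonal discriminant classifiers
#'
#' Diagonal linear discriminant analysis (DLDA) models each class as a
#' Gaussian with a diagonal covariance pooled across classes: per-feature
#' class means, per-feature variances pooled from within-class squared
#' deviations, and empirical class priors. Diagonal quadratic discriminant
#' analysis (DQDA) estimates the diagonal variances per class, giving
#' quadratic boundaries. Variances are floored at `eps` to keep
#' discriminants finite on degenerate features. Empirical (not uniform)
#' priors are used because class imbalance in the biopsy cohort is
#' informative.
#'
#' @param x Numeric matrix or data.frame, samples x features.
#' @param y Labels, `"high"` / `"low"` (both present; at least 2 samples
#'   per class are expected for variance estimation).
#' @param eps Variance floor.
#' @return Object of class `dlda_model` / `dqda_model`.
#' @export
fit_dlda <- function(x, y, eps = 1e-9) {
  d <- check_xy(x, y)
  mu <- do.call(rbind, lapply(classes, function(cl)
    colMeans(d$x[d$y == cl, , drop = FALSE])))
  rownames(mu) <- classes
  ssq <- Reduce(`+`, lapply(classes, function(cl) {
    xc <- d$x[d$y == cl, , drop = FALSE]
    colSums(sweep(xc, 2, colMeans(xc))^2)
  }))
  sigma2 <- pmax(ssq / (nrow(d$x) - 2), eps)
  structure(list(classes = classes, means = mu, sigma2 = sigma2,
                 log_priors = log(as.numeric(table(d$y)[classes]) /
                                  length(d$y)),
                 eps = eps, features = colnames(d$x)),
            class = c("dlda_model", "diag_discriminant"))
}

#' @rdname fit_dlda
#' @export
fit_dqda <- function(x, y, eps = 1e-9) {
  d <- check_xy(x, y)
  mu <- do.call(rbind, lapply(classes, function(cl)
    colMeans(d$x[d$y == cl, , drop = FALSE])))
  rownames(mu) <- classes
  sigma2 <- do.call(rbind, lapply(classes, function(cl) {
    xc <- d$x[d$y == cl, , drop = FALSE]
    pmax(colSums(sweep(xc, 2, colMeans(xc))^2) / max(nrow(xc) - 1, 1),
         eps)
  }))
  rownames(sigma2) <- classes
  structure(list(classes = classes, means = mu, sigma2 = sigma2,
                 log_priors = log(as.numeric(table(d$y)[classes]) /
                                  length(d$y)),
                 eps = eps, features = colnames(d$x)),
            class = c("dqda_model", "diag_discriminant"))
}

# Per-class diagonal-Gaussian log joint density log p(x | c) + log pi_c.
diag_log_joint <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$means))
    stop("feature count mismatch: model has ", ncol(model$means),
         ", input has ", ncol(x))
  vapply(seq_along(model$classes), function(ci) {
    s2 <- if (is.matrix(model$sigma2)) model$sigma2[ci, ] else model$sigma2
    mu <- model$means[ci, ]
    -0.5 * colSums((t(x) - mu)^2 / s2) -
      0.5 * sum(log(2 * pi * s2)) + model$log_priors[ci]
  }, numeric(nrow(x)))
}

#' Predict labels and high-tumor posteriors
#'
#' Posterior probabilities are the normalized exponentiated class log
#' joints (computed stably via the log-sum-exp trick); they sum to 1 over
#' the two classes. The label is the posterior argmax; an exact tie is
#' broken toward `low` — a conservative call, since a false high-tumor
#' call sends a biopsy to a poor target.
#'
#' @param object A `dlda_model` or `dqda_model`.
#' @param newdata Samples x features matrix or data.frame.
#' @param ... Unused.
#' @return `data.frame` with columns `label`, `p_high`, `p_low`.
#' @export
predict.diag_discriminant <- function(object, newdata, ...) {
  lj <- matrix(diag_log_joint(object, newdata), ncol = 2)
  m <- apply(lj, 1, max)
  w <- exp(lj - m)
  post <- w / rowSums(w)
  colnames(post) <- object$classes
  label <- ifelse(post[, "high"] > post[, "low"], "high", "low")
  data.frame(label = label, p_high = post[, "high"],
             p_low = post[, "low"], stringsAsFactors = FALSE)
}

#' Linear support vector machine
#'
#' Wraps a linear-kernel SVM (cost `C`) over features standardized with
#' training statistics. The classifier comparison needs only the decision
#' rule; the reported `p_high` is a logistic squash of the signed margin
#' distance, which is deterministic and monotone in the decision value
#' (not a calibrated probability).
#'
#' @inheritParams fit_dlda
#' @param C Regularization constant.
#' @return Object of class `svm_linear_model`.
#' @export
fit_svm <- function(x, y, C = 1) {
  d <- check_xy(x, y)
  mu <- colMeans(d$x)
  sc <- apply(d$x, 2, stats::sd); sc[sc == 0] <- 1
  z <- sweep(sweep(d$x, 2, mu), 2, sc, "/")
  fit <- e1071::svm(z, d$y, kernel = "linear", cost = C, scale = FALSE)
  structure(list(fit = fit, means = mu, scales = sc, C = C,
                 classes = classes, features = colnames(d$x)),
            class = "svm_linear_model")
}

#' @rdname fit_svm
#' @param object A fitted `svm_linear_model`.
#' @param newdata Samples x features.
#' @param ... Unused.
#' @export
predict.svm_linear_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$means))
    stop("feature count mismatch: model has ", length(object$means),
         ", input has ", ncol(x))
  z <- sweep(sweep(x, 2, object$means), 2, object$scales, "/")
  dvm <- attr(stats::predict(object$fit, z, decision.values = TRUE),
              "decision.values")
  dv <- dvm[, 1]
  # decision.values column is "<first>/<second>"; positive favors the
  # class named first
  if (!grepl("^high", colnames(dvm)[1])) dv <- -dv
  p_high <- 1 / (1 + exp(-dv))
  label <- ifelse(p_high > 0.5, "high", "low")
  data.frame(label = label, p_high = p_high, p_low = 1 - p_high,
             stringsAsFactors = FALSE)
}

#' Fit a classifier by name
#'
#' @param x,y Training data.
#' @param classifier `"dlda"`, `"dqda"` or `"svm"`.
#' @param C SVM cost (ignored otherwise).
#' @return Fitted classifier object.
#' @export
fit_classifier <- function(x, y, classifier = c("dlda", "dqda", "svm"),
                           C = 1) {
  classifier <- match.arg(classifier)
  switch(classifier,
         dlda = fit_dlda(x, y),
         dqda = fit_dqda(x, y),
         svm = fit_svm(x, y, C = C))
}
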