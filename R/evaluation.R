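#' Confusion matrix and derived diagnostic metrics
#'
#' `confusion_matrix()` builds the TP/FP/TN/FN counts ("high" is the
#' positive class); `metrics()` derives accuracy, sensitivity,
#' specificity, PPV and NPV. A ratio with a zero denominator is reported
#' as `NA` (never silently as 0) with an `undefined` attribute naming it.
#'
#' @param truth,pred Label vectors `"high"`/`"low"`.
#' @return `confusion_matrix` object with fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  new_confusion(tp = sum(truth == "high" & pred == "high"),
                fp = sum(truth == "low" & pred == "high"),
                tn = sum(truth == "low" & pred == "low"),
                fn = sum(truth == "high" & pred == "low"))
}

new_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion: tp %d fp %d tn %d fn %d>\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' @rdname confusion_matrix
#' @param cm A `confusion_matrix`.
#' @export
metrics <- function(cm) {
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  if (n == 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- c(accuracy = (cm$tp + cm$tn) / n,
           sensitivity = ratio(cm$tp, cm$tp + cm$fn),
           specificity = ratio(cm$tn, cm$tn + cm$fp),
           ppv = ratio(cm$tp, cm$tp + cm$fp),
           npv = ratio(cm$tn, cm$tn + cm$fn))
  undef <- names(out)[is.na(out)]
  if (length(undef)) attr(out, "undefined") <- undef
  out
}

#' Reconstruct a confusion matrix from printed summary rates
#'
#' Given class counts plus sensitivity and specificity as printed in a
#' summary table, recovers the integer confusion matrix: `tp` is the
#' nearest integer to `sensitivity * n_pos` and `tn` to
#' `specificity * n_neg`, with `fn`/`fp` as complements. The
#' reconstruction is rejected (inconsistency error) if the recovered
#' counts do not reproduce the input rates to within half-count rounding.
#'
#' @param n_pos,n_neg Positive (high-tumor) and negative class counts.
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @param digits Printing precision of the stated rates; the recovered
#'   integer counts must reproduce them at this rounding or the
#'   reconstruction fails with an inconsistency error.
#' @return A `confusion_matrix`.
#' @export
reconstruct_confusion <- function(n_pos, n_neg, sensitivity, specificity,
                                  digits = 3) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  tp <- round(sensitivity * n_pos)
  tn <- round(specificity * n_neg)
  ok <- function(count, n, rate)
    n == 0 || abs(round(count / n, digits) - round(rate, digits)) <=
      10^(-digits) / 2 + 1e-12
  if (!ok(tp, n_pos, sensitivity) || !ok(tn, n_neg, specificity))
    stop("no integer confusion matrix reproduces the stated rates at ",
         digits, "-digit precision")
  new_confusion(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' Reference biopsy-cohort summary table
#'
#' The published summary of the reference GBM biopsy cohort the method was
#' developed on: biopsy counts by zone (enhancing core ENH,
#' brain-around-tumor BAT, Both) and cohort (training n = 60 / 11
#' patients, validation n = 22 / 7 patients), with the printed accuracy,
#' sensitivity, specificity, PPV and NPV of the optimized three-feature
#' model (percent, at one-decimal printing precision). Shipped as plain
#' CSV in `inst/extdata/reference_cohort_table.csv`.
#'
#' @return `data.frame` with one row per cohort x zone.
#' @export
reference_cohort_table <- function() {
  path <- system.file("extdata", "reference_cohort_table.csv",
                      package = "mritexture")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute every reference-table metric from reconstructed counts
#'
#' For each cohort x zone column of the reference summary, reconstructs
#' the integer confusion matrix from the class counts plus printed
#' sensitivity and specificity, recomputes all five metrics, and compares
#' each against the printed cell at one-decimal percent rounding. Also
#' checks zone additivity (Both = ENH + BAT for every count) and derives
#' the pooled (training + validation) prevalence and PPV by zone.
#'
#' @return List with `cells` (per-cell data.frame: printed, recomputed,
#'   match), `n_cells`, `n_matched`, `additivity_ok`, `pooled`
#'   (per-zone pooled prevalence and PPV, percent) and `pass`.
#' @export
check_reference_table <- function() {
  tab <- reference_cohort_table()
  metric_cols <- c("accuracy_pct", "sensitivity_pct", "specificity_pct",
                   "ppv_pct", "npv_pct")
  cells <- NULL
  cms <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    cm <- reconstruct_confusion(row$n_high, row$n_low,
                                row$sensitivity_pct / 100,
                                row$specificity_pct / 100)
    cms[[paste(row$cohort, row$zone)]] <- cm
    got <- metrics(cm) * 100
    names(got) <- metric_cols
    for (mc in metric_cols) {
      cells <- rbind(cells, data.frame(
        cohort = row$cohort, zone = row$zone, metric = mc,
        printed = row[[mc]], recomputed = got[[mc]],
        match = round(got[[mc]], 1) == round(row[[mc]], 1),
        stringsAsFactors = FALSE))
    }
  }
  additivity_ok <- all(vapply(c("training", "validation"), function(co) {
    s <- tab[tab$cohort == co, ]
    both <- s[s$zone == "Both", ]
    enh <- s[s$zone == "ENH", ]; bat <- s[s$zone == "BAT", ]
    both$n_total == enh$n_total + bat$n_total &&
      both$n_high == enh$n_high + bat$n_high &&
      both$n_low == enh$n_low + bat$n_low
  }, TRUE))
  pooled <- lapply(c(ENH = "ENH", BAT = "BAT"), function(z) {
    s <- tab[tab$zone == z, ]
    cm2 <- lapply(paste(s$cohort, z), function(k) cms[[k]])
    tp <- sum(vapply(cm2, `[[`, 0, "tp"))
    fp <- sum(vapply(cm2, `[[`, 0, "fp"))
    c(prevalence_pct = 100 * sum(s$n_high) / sum(s$n_total),
      ppv_pct = 100 * tp / (tp + fp))
  })
  list(cells = cells, n_cells = nrow(cells),
       n_matched = sum(cells$match), additivity_ok = additivity_ok,
       pooled = pooled,
       pass = all(cells$match) && additivity_ok)
}

#' Evaluate a trained model on a validation feature table
#'
#' Applies the training-fitted reduction and classifier (no component is
#' refitted) and reports confusion metrics stratified by zone (ENH, BAT)
#' and overall (Both).
#'
#' @param model A [tumor_content_model()].
#' @param features Validation feature `data.frame` with metadata (`zone`,
#'   `label`) and the 256 feature columns.
#' @return `data.frame` of metrics per zone, plus a `confusions`
#'   attribute.
#' @export
evaluate_on_validation <- function(model, features) {
  pred <- stats::predict(model, features)$label
  truth <- features$label
  zones <- list(ENH = features$zone == "ENH",
                BAT = features$zone == "BAT",
                Both = rep(TRUE, nrow(features)))
  cms <- lapply(zones, function(idx)
    confusion_matrix(truth[idx], pred[idx]))
  out <- do.call(rbind, lapply(names(cms), function(z) {
    m <- metrics(cms[[z]])
    data.frame(zone = z, n = sum(zones[[z]]), t(m),
               stringsAsFactors = FALSE)
  }))
  attr(out, "confusions") <- cms
  out
}

#' Exclude biopsies lying too close to a neighbor
#'
#' Iteratively removes the minimum number of same-patient sites so that no
#' pair remains with 3D physical center distance in `[min_mm, max_mm)`.
#' Greedy heuristic: repeatedly drop the site participating in the most
#' offending pairs (ties broken by site order); validated against an
#' exhaustive minimal-removal search at toy scale.
#'
#' @param sites List of `biopsy_site`s.
#' @param min_mm,max_mm Offending distance band in mm (default 5-10 mm).
#' @param voxel_size_mm `(dz, dy, dx)` voxel size.
#' @return Filtered site list with attribute `removed` (indices dropped).
#' @export
exclude_close_pairs <- function(sites, min_mm = 5, max_mm = 10,
                                voxel_size_mm = c(3, 1.2, 1.2)) {
  n <- length(sites)
  if (n == 0) return(sites)
  centers <- t(vapply(sites, function(s)
    site_center_mm(s$slice, s$row0, s$col0, voxel_size_mm), numeric(3)))
  pid <- vapply(sites, `[[`, "", "patient_id")
  offend <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (pid[i] != pid[j]) next
    d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
    if (d >= min_mm && d < max_mm) offend[i, j] <- offend[j, i] <- TRUE
  }
  keep <- rep(TRUE, n)
  repeat {
    deg <- rowSums(offend[keep, keep, drop = FALSE])
    if (!length(deg) || all(deg == 0)) break
    worst <- which(keep)[which.max(deg)]   # first max = earliest site
    keep[worst] <- FALSE
  }
  out <- sites[keep]
  attr(out, "removed") <- which(!keep)
  out
}
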