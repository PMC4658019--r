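test_that("metrics reproduce the reference training and validation columns", {
  # training, both zones pooled
  m <- metrics(mritexture:::new_confusion(tp = 23, fp = 5, tn = 28,
                                          fn = 4))
  expect_equal(unname(m["accuracy"]), 0.850)
  expect_equal(unname(m["ppv"]), 0.8214, tolerance = 5e-4)
  expect_equal(unname(m["npv"]), 0.875)
  # validation, both zones pooled
  v <- metrics(mritexture:::new_confusion(tp = 9, fp = 4, tn = 9,
                                          fn = 0))
  expect_equal(unname(v["accuracy"]), 0.8182, tolerance = 5e-4)
  expect_equal(unname(v["sensitivity"]), 1.0)
  expect_equal(unname(v["npv"]), 1.0)
})

test_that("undefined ratios surface as NA, never silently as zero", {
  m <- metrics(mritexture:::new_confusion(tp = 10, fp = 0, tn = 0,
                                          fn = 0))
  expect_equal(unname(m["accuracy"]), 1)
  expect_equal(unname(m["sensitivity"]), 1)
  expect_equal(unname(m["ppv"]), 1)
  expect_true(is.na(m["specificity"]))
  expect_true("specificity" %in% attr(m, "undefined"))
  expect_error(metrics(mritexture:::new_confusion(0, 0, 0, 0)), "empty")
})

test_that("confusion matrices reconstruct from printed rates", {
  cm <- reconstruct_confusion(22, 13, 0.864, 0.769)
  expect_equal(cm$tp, 19); expect_equal(cm$fn, 3)
  expect_equal(cm$tn, 10); expect_equal(cm$fp, 3)
  cm2 <- reconstruct_confusion(5, 20, 0.80, 0.90)
  expect_equal(cm2$tp, 4); expect_equal(cm2$tn, 18)
  cm3 <- reconstruct_confusion(17, 9, 1, 1)
  expect_equal(cm3$fn + cm3$fp, 0)
  # rates no integer matrix reproduces at the stated printing precision
  expect_error(reconstruct_confusion(3, 3, 0.70, 0.5),
               "no integer confusion")
})

test_that("confusion counts from labels add up", {
  truth <- c("high", "high", "low", "low", "high")
  pred <- c("high", "low", "low", "high", "high")
  cm <- confusion_matrix(truth, pred)
  expect_equal(cm$tp, 2); expect_equal(cm$fn, 1)
  expect_equal(cm$tn, 1); expect_equal(cm$fp, 1)
})

test_that("close-pair exclusion is idle when all sites are far apart", {
  sites <- lapply(0:3, function(i)
    biopsy_site("P01", 0, i * 12, 0, "ENH", 50))
  out <- exclude_close_pairs(sites)
  expect_length(out, 4L)
  expect_length(attr(out, "removed"), 0L)
})

test_that("greedy exclusion removes as few sites as the exhaustive oracle", {
  vox <- c(3, 1.2, 1.2)
  mk <- function(row0, col0, slice = 0, pid = "P01")
    biopsy_site(pid, slice, row0, col0, "ENH", 50)
  # layout with two offending pairs sharing one site, plus satellites
  layouts <- list(
    list(mk(0, 0), mk(6, 0), mk(12, 0), mk(40, 0), mk(0, 40), mk(40, 40)),
    list(mk(0, 0), mk(5, 0), mk(0, 5), mk(30, 30), mk(36, 30), mk(30, 36)),
    list(mk(0, 0), mk(6, 0), mk(0, 6), mk(6, 6), mk(40, 40), mk(20, 20)))
  for (sites in layouts) {
    kept <- exclude_close_pairs(sites, 5, 10, vox)
    expect_equal(length(kept),
                 oracle_min_removal(sites, 5, 10, vox))
    # no offending pair remains
    expect_length(attr(exclude_close_pairs(kept, 5, 10, vox), "removed"),
                  0L)
  }
})

test_that("a 60-site cohort with 6 close biopsies filters to 54", {
  # cohort layout: 54 well-separated sites plus 6 placed 5-10 mm from a
  # distinct far site, mirroring the subgroup-exclusion scenario
  sites <- list()
  for (p in 1:6) for (i in 1:9) {
    sites <- c(sites, list(biopsy_site(sprintf("P%02d", p), (i - 1) %% 3,
                                       20 * ((i - 1) %/% 3), 20 * ((i - 1) %% 3),
                                       "ENH", 50)))
  }
  stopifnot(length(sites) == 54)
  offenders <- lapply(1:6, function(p)
    biopsy_site(sprintf("P%02d", p), 0, 5, 0, "BAT", 30))
  all60 <- c(sites, offenders)
  kept <- exclude_close_pairs(all60, 5, 10, c(3, 1.2, 1.2))
  expect_length(kept, 54L)
  expect_length(attr(kept, "removed"), 6L)
})

test_that("validation on the training set reproduces resubstitution", {
  cc <- cohort_config(n_patients = 2L, volume_shape = c(8L, 48L, 48L),
                      n_biopsies_per_patient = 6L, seed = 31)
  coh <- generate_cohort(cc)
  feats <- extract_features(coh$volumes, coh$sites)
  model <- tumor_content_model(feats)
  res <- evaluate_on_validation(model, feats)
  pred <- predict(model, feats)$label
  cm <- confusion_matrix(feats$label, pred)
  both <- res[res$zone == "Both", ]
  expect_equal(both$accuracy, unname(metrics(cm)["accuracy"]))
  # zone additivity of counts
  cms <- attr(res, "confusions")
  for (f in c("tp", "fp", "tn", "fn"))
    expect_equal(cms$Both[[f]], cms$ENH[[f]] + cms$BAT[[f]])
})
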