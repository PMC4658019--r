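# Small, fast cohort configuration used across tests.
test_config <- function(...) {
  cohort_config(n_patients = 2L, volume_shape = c(8L, 48L, 48L),
                n_biopsies_per_patient = 4L, ...)
}

test_that("patient generation is bit-reproducible and well-formed", {
  cc <- test_config(seed = 5)
  a <- generate_patient(cc, 1)
  b <- generate_patient(cc, 1)
  for (cn in contrast_names())
    expect_identical(a$volumes[[cn]]$data, b$volumes[[cn]]$data)
  expect_identical(a$field$tumor_fraction, b$field$tumor_fraction)
  # different patients differ
  c2 <- generate_patient(cc, 2)
  expect_false(identical(a$volumes[["T2W"]]$data,
                         c2$volumes[["T2W"]]$data))
  # contract: 8 contrasts on one grid, masks disjoint, fraction in range
  expect_setequal(names(a$volumes), contrast_names())
  dims <- vapply(a$volumes, function(v) dim(v$data), integer(3))
  expect_true(all(dims == dims[, 1]))
  expect_false(any(a$field$enh_mask & a$field$bat_mask))
  expect_true(all(a$field$tumor_fraction >= 0 &
                  a$field$tumor_fraction <= 100))
})

test_that("the rCBV shift recovers effect_rcbv against a direct redraw", {
  cc <- test_config(seed = 21, effect_rcbv = 1.0)
  pat <- generate_patient(cc, 1)
  high <- pat$field$tumor_fraction >= 80
  enh_high <- high & pat$field$enh_mask
  low <- !high
  diff_obs <- mean(pat$volumes$rCBV$data[enh_high]) -
    mean(pat$volumes$rCBV$data[low & pat$field$enh_mask])
  # direct simulation of the same generative draw: unit-variance noise
  # plus a 1-SD shift; Monte-Carlo standard error bound
  se <- sqrt(1 / sum(enh_high) + 1 / sum(low & pat$field$enh_mask))
  expect_lt(abs(diff_obs - 1.0), 5 * se)
})

test_that("zeroed effects remove every class-conditional difference", {
  cc <- test_config(seed = 22, effect_rcbv = 0,
                    t1c_pattern_amplitude = 0,
                    texture_scale_low = 1.5, texture_scale_high = 1.5)
  pat <- generate_patient(cc, 1)
  high <- pat$field$tumor_fraction >= 80
  # same marginal distribution: two-sample KS on rCBV and T1+C
  for (cn in c("rCBV", "T1+C")) {
    v <- pat$volumes[[cn]]$data
    ks <- suppressWarnings(stats::ks.test(sample(v[high], 500),
                                          sample(v[!high], 500)))
    expect_gt(ks$p.value, 1e-4)
  }
})

test_that("biopsy sites respect spacing, zones and footprint labels", {
  cc <- test_config(seed = 23, min_spacing_mm = 10)
  pat <- generate_patient(cc, 1)
  set.seed(1)
  sites <- sample_biopsy_sites(pat$field, cc, "P01", 5)
  expect_length(sites, 5L)
  # brute-force pairwise distance check in physical mm
  ctr <- t(sapply(sites, function(s)
    c(s$slice * 3, (s$row0 + 3.5) * 1.2, (s$col0 + 3.5) * 1.2)))
  for (i in 1:4) for (j in (i + 1):5)
    expect_gte(sqrt(sum((ctr[i, ] - ctr[j, ])^2)), 10)
  # recorded percent tumor nuclei is the footprint mean
  s1 <- sites[[1]]
  expect_equal(s1$pct_tumor_nuclei,
               mean(pat$field$tumor_fraction[
                 s1$slice + 1, (s1$row0 + 1):(s1$row0 + 8),
                 (s1$col0 + 1):(s1$col0 + 8)]))
})

test_that("enh_fraction = 1 keeps every footprint inside the ENH mask", {
  cc <- test_config(seed = 24, enh_fraction = 1, min_spacing_mm = 0)
  pat <- generate_patient(cc, 1)
  set.seed(2)
  sites <- sample_biopsy_sites(pat$field, cc, "P01", 4)
  for (s in sites) {
    expect_equal(s$zone, "ENH")
    foot <- pat$field$enh_mask[s$slice + 1, (s$row0 + 1):(s$row0 + 8),
                               (s$col0 + 1):(s$col0 + 8)]
    expect_true(all(foot))
  }
})

test_that("unsatisfiable spacing fails with a named constraint", {
  cc <- test_config(seed = 25, min_spacing_mm = 500)
  pat <- generate_patient(cc, 1)
  set.seed(3)
  expect_error(sample_biopsy_sites(pat$field, cc, "P01", 4),
               "min_spacing_mm")
})

test_that("zone prevalence is ordered ENH above BAT under defaults", {
  coh <- generate_cohort(cohort_config(seed = 26, n_patients = 6))
  zones <- vapply(coh$sites, `[[`, "", "zone")
  labels <- vapply(coh$sites, `[[`, "", "label")
  p_enh <- mean(labels[zones == "ENH"] == "high")
  p_bat <- mean(labels[zones == "BAT"] == "high")
  expect_gt(p_enh, p_bat)
})

test_that("cohorts round-trip through the NIfTI + CSV writers", {
  cc <- test_config(seed = 27)
  coh <- generate_cohort(cc, n_patients = 1, n_sites_total = 3)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$volumes$P01$rCBV$data, coh$volumes$P01$rCBV$data,
               tolerance = 1e-6)
  expect_length(back$sites, 3L)
  expect_equal(back$sites[[2]]$pct_tumor_nuclei,
               coh$sites[[2]]$pct_tumor_nuclei, tolerance = 1e-10)
})
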