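# GLCM ------------------------------------------------------------------

test_that("constant patch gives the degenerate single-cell GLCM", {
  f <- compute_glcm_features(roi_patch("T2W", matrix(9, 8, 8)))
  expect_equal(length(f), 13L)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["dissimilarity"]), 0)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["correlation"]), 0)  # zero-variance convention
})

test_that("GLCM features equal the exhaustive pair-count oracle", {
  set.seed(42)
  for (i in 1:100) {
    p <- random_patch()
    for (lev in c(8L, 16L)) {
      expect_equal(compute_glcm_features(p, lev),
                   oracle_glcm_features(p$rescaled, lev),
                   tolerance = 1e-12)
    }
  }
})

test_that("GLCM features are invariant to 90-degree rotation and transpose", {
  set.seed(3)
  for (i in 1:20) {
    p <- random_patch()
    pr <- roi_patch("T1+C", rotate90(p$raw))
    pt <- roi_patch("T1+C", t(p$raw))
    expect_equal(compute_glcm_features(p), compute_glcm_features(pr),
                 tolerance = 1e-12)
    expect_equal(compute_glcm_features(p), compute_glcm_features(pt),
                 tolerance = 1e-12)
  }
})

test_that("checkerboard structure shows in contrast and matches oracle", {
  raw <- outer(1:8, 1:8, function(i, j) (i + j) %% 2) * 100
  p <- roi_patch("p", raw)
  f <- compute_glcm_features(p)
  expect_equal(f, oracle_glcm_features(p$rescaled), tolerance = 1e-12)
  expect_gt(f["contrast"], 0)
  # axial offsets anti-correlate, diagonal offsets correlate perfectly;
  # the 4-angle average cancels exactly
  expect_equal(unname(f["correlation"]), 0, tolerance = 1e-12)
})

# LBP -------------------------------------------------------------------

test_that("constant patch puts all LBP mass in the top uniform bin", {
  h <- compute_lbp_features(roi_patch("FA", matrix(1, 8, 8)))
  expect_equal(length(h), 12L)
  expect_equal(sum(h), 1)
  expect_equal(unname(h["bin11"]), 1)  # 24 set bits -> last uniform bin
})

test_that("LBP histogram equals the explicit-rotation oracle", {
  set.seed(11)
  for (i in 1:100) {
    p <- random_patch()
    expect_equal(unname(compute_lbp_features(p)),
                 oracle_lbp_features(p$rescaled), tolerance = 1e-12)
  }
})

test_that("LBP is invariant to affine intensity maps and rotation", {
  # with bilinearly interpolated sample points the ordinal-invariance of
  # LBP is exact for positive affine maps (nonlinear monotone maps move
  # interpolated values); rotation by quarter turns is exact because the
  # 24 sample points map onto each other
  set.seed(5)
  for (i in 1:20) {
    p <- random_patch()
    aff <- roi_patch("q", 2.5 * p$raw + 3)
    rot <- roi_patch("q", rotate90(p$raw))
    expect_equal(compute_lbp_features(p), compute_lbp_features(aff),
                 tolerance = 1e-12)
    expect_equal(compute_lbp_features(p), compute_lbp_features(rot),
                 tolerance = 1e-9)
  }
})

# DOST ------------------------------------------------------------------

test_that("constant patch has a DC-only spectrum", {
  f <- compute_dost_features(roi_patch("MD", matrix(5, 8, 8)))
  expect_equal(length(f), 5L)
  expect_equal(unname(f["dc"]), 64 * 5)   # DC amplitude proportional to c
  expect_equal(unname(f[c("band1", "band2", "band3")]), c(0, 0, 0))
  expect_equal(unname(f["spectral_entropy"]), 0)
  # all-zero patch stays finite
  expect_true(all(is.finite(
    compute_dost_features(roi_patch("MD", matrix(0, 8, 8))))))
})

test_that("DOST features equal the naive O(N^4) DFT oracle, with Parseval", {
  set.seed(23)
  for (i in 1:25) {
    p <- random_patch()
    expect_equal(unname(compute_dost_features(p)),
                 oracle_dost_features(p$raw), tolerance = 1e-8)
    # Parseval with the unnormalized forward transform
    expect_equal(sum(Mod(oracle_dft2(p$raw))^2), 64 * sum(p$raw^2),
                 tolerance = 1e-8)
  }
})

test_that("DOST radial features are invariant under 90-degree rotation", {
  set.seed(31)
  for (i in 1:20) {
    p <- random_patch()
    pr <- roi_patch("T1+C", rotate90(p$raw))
    expect_equal(compute_dost_features(p), compute_dost_features(pr),
                 tolerance = 1e-9)
  }
})

# Assembly --------------------------------------------------------------

test_that("feature vector has 256 named entries, 30 texture per contrast", {
  set.seed(2)
  patches <- lapply(contrast_names(), function(cn) random_patch(cn))
  names(patches) <- contrast_names()
  fv <- assemble_feature_vector(patches)
  expect_equal(length(fv), 256L)
  expect_equal(names(fv), feature_registry())
  for (cn in contrast_names()) {
    tex <- grep(paste0("^", gsub("\\+", "\\\\+", cn),
                       "__(GLCM|LBP|DOST)__"), names(fv))
    expect_equal(length(tex), 30L)   # 13 + 12 + 5
  }
  expect_equal(sum(grepl("__RAW__", names(fv))), 16L)
})

test_that("missing contrast fails assembly by name", {
  patches <- lapply(contrast_names(), function(cn) random_patch(cn))
  names(patches) <- contrast_names()
  expect_error(assemble_feature_vector(patches[-3]), "rCBV")
})

test_that("feature blocks tile the registry exactly once", {
  blocks <- do.call(c, lapply(seq_len(nrow(mritexture:::feature_blocks())),
    function(b) {
      bl <- mritexture:::feature_blocks()[b, ]
      mritexture:::block_columns(bl$contrast, bl$algorithm)
    }))
  expect_setequal(blocks, feature_registry())
  expect_equal(anyDuplicated(blocks), 0L)
})
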