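# Build a feature table whose named block has prescribed structure and
# the rest is noise.
synth_features <- function(n, block_fun = NULL, block = c("T2W", "GLCM")) {
  set.seed(99)
  x <- matrix(rnorm(n * 256), n, 256,
              dimnames = list(NULL, feature_registry()))
  if (!is.null(block_fun)) {
    cols <- mritexture:::block_columns(block[1], block[2])
    x[, cols] <- block_fun(n, length(cols))
  }
  as.data.frame(x, check.names = FALSE)
}

test_that("a rank-1 block retains one component explaining everything", {
  f <- synth_features(30, function(n, p) {
    s <- rnorm(n)
    outer(s, seq_len(p))          # scalar multiples of one signal
  })
  red <- fit_reduction(f)
  m <- red$models[["T2W__GLCM"]]
  expect_equal(m$k, 1L)
  expect_equal(m$explained, 1.0, tolerance = 1e-9)
})

test_that("the 85% rule matches a hand eigendecomposition", {
  # unit-diagonal correlation matrix with eigenvalues (1.8, 0.9, 0.3) —
  # the (6,3,1)/10 spectrum rescaled to trace 3 — so the cumulative
  # variance fractions are 0.6, 0.9, 1.0 and the 85% rule keeps 2
  set.seed(4)
  n <- 4000
  a <- sqrt(0.56 / 2); b <- 0.1
  C <- matrix(c(1, a, b, a, 1, a, b, a, 1), 3)
  expect_equal(sort(eigen(C)$values, decreasing = TRUE),
               c(1.8, 0.9, 0.3), tolerance = 1e-9)
  z <- matrix(rnorm(n * 3), n, 3) %*% chol(C)
  cumfrac <- cumsum(sort(eigen(cor(z))$values, decreasing = TRUE)) / 3
  k_oracle <- which(cumfrac >= 0.85)[1]
  expect_equal(k_oracle, 2L)      # 0.6, 0.9 -> two components
  # run the block machinery on a table whose DOST block holds 3 live
  # features (the other 2 constant so they contribute nothing)
  f <- synth_features(n, function(nn, p) {
    cbind(z[seq_len(nn), ], matrix(1, nn, p - 3))
  }, block = c("FA", "DOST"))
  red <- fit_reduction(f)
  expect_equal(red$models[["FA__DOST"]]$k, k_oracle)
})

test_that("every texture block retains at least 85% variance", {
  f <- synth_features(40)
  red <- fit_reduction(f)
  for (m in red$models)
    if (!m$passthrough) {
      expect_gte(m$explained, 0.85)
      expect_gte(m$k, 1L)
      expect_lte(m$k, length(m$columns))
      # loadings orthonormal
      expect_equal(crossprod(m$loadings),
                   diag(m$k), tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
})

test_that("training transform reproduces the retained eigenvalues", {
  f <- synth_features(50)
  red <- fit_reduction(f)
  scores <- transform_features(red, f)
  for (id in names(red$models)) {
    m <- red$models[[id]]
    if (m$passthrough) next
    v <- apply(scores[, m$out_names, drop = FALSE], 2, var)
    expect_equal(unname(v), m$eigenvalues, tolerance = 1e-8)
    # scores mutually uncorrelated within a block
    if (m$k > 1) {
      cc <- cor(scores[, m$out_names])
      expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
    }
  }
})

test_that("a sample at the training mean maps to zero PC scores", {
  f <- synth_features(25)
  red <- fit_reduction(f)
  mu <- as.data.frame(t(colMeans(as.matrix(f))), check.names = FALSE)
  sc <- transform_features(red, mu)
  pc_cols <- grep("__PC", names(sc))
  expect_true(all(abs(sc[, pc_cols]) < 1e-8))
})

test_that("validation data use stored training statistics, no refit", {
  f <- synth_features(25)
  red <- fit_reduction(f)
  shifted <- f
  shifted[, "T2W__RAW__mean"] <- shifted[, "T2W__RAW__mean"] + 10
  s0 <- transform_features(red, f)
  s1 <- transform_features(red, shifted)
  sds <- sd(f[, "T2W__RAW__mean"])
  expect_equal(s1[, "T2W__raw_mean"] - s0[, "T2W__raw_mean"],
               rep(10 / sds, 25), tolerance = 1e-8)
  # untouched blocks are untouched
  expect_equal(s1[, "FA__raw_mean"], s0[, "FA__raw_mean"])
})

test_that("reduction rejects tiny or incomplete inputs", {
  f <- synth_features(10)
  expect_error(fit_reduction(f[1:2, ]), "at least 3")
  expect_error(transform_features(fit_reduction(f), f[, -5]),
               "missing")
})

test_that("reduction serializes to JSON and back", {
  f <- synth_features(20)
  red <- fit_reduction(f)
  path <- file.path(tempdir(), "red.json")
  write_reduction(red, path)
  back <- read_reduction(path)
  expect_equal(transform_features(back, f), transform_features(red, f),
               tolerance = 1e-10)
})
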