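test_that("histogram features hit closed forms on degenerate ROIs", {
  q1 <- make_qroi(array(1L, c(3, 3, 2)), ng = 64)
  h1 <- histogram_features(q1)
  expect_equal(unname(h1[c("Entropy", "Uniformity", "Variance",
                           "Skewness", "Kurtosis")]), c(0, 1, 0, 0, 0))

  q2 <- make_qroi(array(c(1L, 2L), c(2, 2, 2)), ng = 2)
  h2 <- histogram_features(q2)
  expect_equal(unname(h2["Entropy"]), 1)      # two equiprobable levels: 1 bit
  expect_equal(unname(h2["Uniformity"]), 0.5)
})

test_that("histogram features match brute-force recomputation to 1e-12", {
  set.seed(7)
  lev <- array(sample(0:8, 200, replace = TRUE), c(10, 5, 4))
  if (!any(lev > 0)) lev[1] <- 1L
  q <- make_qroi(lev, ng = 8)
  h <- histogram_features(q)
  v <- as.numeric(lev[lev > 0])
  mu <- mean(v)
  p <- table(factor(v, levels = 1:8)) / length(v)
  expect_equal(unname(h["Mean"]), mu, tolerance = 1e-12)
  expect_equal(unname(h["Variance"]), mean((v - mu)^2), tolerance = 1e-12)
  expect_equal(unname(h["Skewness"]), samp_skew(v), tolerance = 1e-12)
  expect_equal(unname(h["Kurtosis"]),
               mean((v - mu)^4) / mean((v - mu)^2)^2, tolerance = 1e-12)
  expect_equal(unname(h["Energy"]), mean(v^2), tolerance = 1e-12)
  expect_equal(unname(h["Entropy"]),
               -sum(p[p > 0] * log2(p[p > 0])), tolerance = 1e-12)
  expect_equal(unname(h["Uniformity"]), sum(p^2), tolerance = 1e-12)
})

test_that("GLCM matches exhaustive pair enumeration", {
  # constant ROI: single nonzero entry
  qc <- make_qroi(array(1L, c(3, 3, 1)), ng = 4)
  mc <- glcm_matrix(qc)
  expect_true(all(mc[-1, ] == 0) && all(mc[, -1] == 0))
  fc <- glcm_features(mc)
  expect_equal(unname(fc[c("Contrast", "Dissimilarity", "Energy")]),
               c(0, 0, 1))

  # 2x2x1 worked example
  q2 <- make_qroi(array(c(1L, 1L, 2L, 2L), c(2, 2, 1)), ng = 2)
  expect_equal(glcm_matrix(q2), oracle_glcm(q2$levels, 2))

  # random ROIs vs the triple-loop oracle
  set.seed(11)
  for (rep in 1:5) {
    q <- random_qroi(ng = 5, max_dim = c(5, 5, 3))
    expect_equal(glcm_matrix(q), oracle_glcm(q$levels, 5))
  }
  # distance 2
  q <- random_qroi(ng = 4, max_dim = c(6, 6, 4))
  expect_equal(glcm_matrix(q, distance = 2),
               oracle_glcm(q$levels, 4, distance = 2))
})

test_that("single-voxel ROIs raise the no-pairs signal", {
  lev <- array(0L, c(3, 3, 3)); lev[2, 2, 2] <- 1L
  expect_error(glcm_matrix(make_qroi(lev, 2)), "no pairs")
})

test_that("GLRLM matches run-scanning oracle, merged and per direction", {
  # constant 1x1x4 ROI along z: direction 3 is (0,0,1)
  lev <- array(1L, c(1, 1, 4))
  qz <- make_qroi(lev, ng = 2)
  mz <- glrlm_matrix(qz, directions = 3)
  expect_equal(mz[1, 4], 1)
  expect_equal(sum(mz), 1)        # one run of length 4
  f <- glrlm_features(mz)
  expect_equal(unname(f["RP"]), 1 / 4)

  # all-distinct levels on a line: every run has length 1, SRE = 1
  qd <- make_qroi(array(1:4, c(4, 1, 1)), ng = 4)
  fd <- glrlm_features(glrlm_matrix(qd, directions = 1))
  expect_equal(unname(fd["SRE"]), 1)

  set.seed(13)
  for (rep in 1:5) {
    q <- random_qroi(ng = 4, max_dim = c(4, 4, 2))
    got <- glrlm_matrix(q)
    exp_m <- oracle_glrlm(q$levels, 4)
    expect_equal(unclass(got)[, seq_len(ncol(exp_m)), drop = FALSE],
                 exp_m, ignore_attr = TRUE)
    for (d in c(1, 5, 10))
      expect_equal(unclass(glrlm_matrix(q, directions = d)),
                   oracle_glrlm(q$levels, 4, dirs = d),
                   ignore_attr = TRUE)
  }
})

test_that("GLSZM zones match the flood-fill oracle", {
  # constant ROI: one zone of size n, ZP = 1/n
  qc <- make_qroi(array(2L, c(3, 3, 2)), ng = 3)
  m <- glszm_matrix(qc)
  expect_equal(sum(m), 1)
  expect_equal(m[2, 18], 1)
  expect_equal(unname(glszm_features(m)["ZP"]), 1 / 18)

  # checkerboard: diagonal 26-connectivity joins equal levels -> 2 zones
  cb <- array(0L, c(4, 4, 1))
  for (x in 1:4) for (y in 1:4) cb[x, y, 1] <- 1L + (x + y) %% 2L
  zq <- make_qroi(cb, ng = 2)
  zones <- oracle_glszm(zq$levels)
  expect_equal(nrow(zones), 2)
  mcb <- glszm_matrix(zq)
  expect_equal(sum(mcb), 2)
  expect_equal(mcb[1, 8], 1)  # 8 voxels of each level, one zone each
  expect_equal(mcb[2, 8], 1)

  set.seed(17)
  for (rep in 1:5) {
    q <- random_qroi(ng = 3, max_dim = c(5, 5, 2))
    zones <- oracle_glszm(q$levels)
    m <- glszm_matrix(q)
    # rebuild the matrix from the oracle zone list
    m2 <- matrix(0, 3, ncol(m))
    for (r in seq_len(nrow(zones)))
      m2[zones[r, 1], zones[r, 2]] <- m2[zones[r, 1], zones[r, 2]] + 1
    expect_equal(unclass(m), m2, ignore_attr = TRUE)
  }
})

test_that("NGTDM matches the neighbourhood-loop oracle", {
  # flat ROI: all s = 0, coarseness capped at 1/eps
  qc <- make_qroi(array(1L, c(3, 3, 1)), ng = 2)
  mc <- ngtdm_matrix(qc)
  expect_equal(unname(mc[, "s"]), c(0, 0))
  expect_equal(unname(ngtdm_features(mc)["Coarseness"]), 1e12)

  # single bright voxel in a flat 3x3 plane: its 8 neighbours average 1
  lev <- array(1L, c(3, 3, 1)); lev[2, 2, 1] <- 2L
  mq <- ngtdm_matrix(make_qroi(lev, ng = 2))
  expect_equal(unname(mq[2, "s"]), abs(2 - 1))
  expect_equal(unclass(mq), oracle_ngtdm(lev, 2), ignore_attr = TRUE)

  set.seed(19)
  for (rep in 1:5) {
    q <- random_qroi(ng = 4, max_dim = c(5, 5, 3))
    expect_equal(unclass(ngtdm_matrix(q)), oracle_ngtdm(q$levels, 4),
                 ignore_attr = TRUE)
  }
})

test_that("the default registry yields 423 unique finite features", {
  expect_length(feature_names(), 423)
  expect_false(anyDuplicated(feature_names()) > 0)
  tm <- small_tumor(seed = 41)
  fv <- extract_all(tm$volume, tm$mask)
  expect_named(fv, feature_names())
  expect_true(all(is.finite(fv)))
  # identical cases give identical vectors
  fv2 <- extract_all(tm$volume, tm$mask)
  expect_identical(fv, fv2)
})

test_that("features are invariant to affine intensity rescaling", {
  tm <- small_tumor(seed = 42)
  fv <- extract_all(tm$volume, tm$mask)
  v2 <- image_volume(2 * tm$volume$data, tm$volume$spacing)
  fv2 <- extract_all(v2, tm$mask)
  orig <- !grepl("^(LLL|LLH|LHL|LHH|HLL|HLH|HHL|HHH)_", names(fv))
  expect_equal(fv[orig], fv2[orig], tolerance = 1e-10)
})

test_that("histogram entropy and uniformity respect their bounds", {
  set.seed(23)
  for (rep in 1:10) {
    q <- random_qroi(ng = 64, max_dim = c(8, 8, 4))
    h <- histogram_features(q)
    expect_gte(h[["Entropy"]], 0)
    expect_lte(h[["Entropy"]], log2(64))
    expect_gte(h[["Uniformity"]], 1 / 64)
    expect_lte(h[["Uniformity"]], 1)
  }
})

test_that("a constant-ROI case flows through extraction with the conventions", {
  sp <- class_spec("SCA", hist_levels_active = 1)
  tm <- generate_tumor(sp, shape_mm = c(30, 30, 40), seed = 43)
  fv <- extract_all(tm$volume, tm$mask)
  expect_equal(unname(fv["Histogram_Entropy"]), 0)
  expect_equal(unname(fv["Histogram_Uniformity"]), 1)
  expect_true(all(is.finite(fv)))
})
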