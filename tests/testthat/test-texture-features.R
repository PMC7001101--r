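test_that("equal-width quantization follows the stated binning rule", {
  sp <- c(1, 1, 1)
  vol <- image_volume(array(c(0, 1, 2, 3), c(4, 1, 1)), sp)
  msk <- voi_mask(array(TRUE, c(4, 1, 1)), sp)
  q <- quantize(vol, msk, 2)
  expect_identical(as.vector(q$levels), c(1L, 1L, 2L, 2L))

  const <- image_volume(array(5, c(3, 3, 1)), sp)
  cm <- voi_mask(array(TRUE, c(3, 3, 1)), sp)
  expect_true(all(quantize(const, cm, 8)$levels == 1L))

  # min-max affine transform leaves the levels unchanged
  set.seed(7)
  v <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  m <- voi_mask(array(runif(length(v)) < 0.6, dim(v)), sp)
  q1 <- quantize(image_volume(v, sp), m, 16)
  q2 <- quantize(image_volume(3.7 * v - 11, sp), m, 16)
  expect_identical(q1$levels, q2$levels)

  expect_error(quantize(const, voi_mask(array(FALSE, c(3, 3, 1)), sp), 8),
               "empty")
  expect_error(quantize(const, cm, 1), ">= 2")
})

test_that("the worked 4x4 co-occurrence matrix is reproduced exactly", {
  grey <- rbind(c(0, 0, 1, 1),
                c(0, 0, 1, 1),
                c(0, 2, 2, 2),
                c(2, 2, 3, 3))
  # horizontal = within a row: store rows along the first axis so the
  # displacement (0,1,0) walks along each row; also check via transpose
  lev <- array(as.integer(grey + 1), c(4, 4, 1))
  g <- build_glcm(make_qvoi(lev, 4), c(0, 1, 0))
  expect_equal(g$pair_count, 24)
  # hand enumeration (symmetrized counts / 24)
  expected <- matrix(c(4, 2, 1, 0,
                       2, 4, 0, 0,
                       1, 0, 6, 1,
                       0, 0, 1, 2) / 24, 4, 4, byrow = TRUE)
  expect_equal(g$p, expected)
  expect_equal(g$p[1, 1], 1 / 6)
  expect_equal(sum(g$p), 1, tolerance = 1e-12)
  expect_equal(g$p, t(g$p))

  g_t <- build_glcm(make_qvoi(array(as.integer(t(grey + 1)), c(4, 4, 1)), 4),
                    c(1, 0, 0))
  expect_equal(g_t$p, expected)
})

test_that("strip and constant GLCMs match hand enumeration", {
  strip <- array(c(1L, 2L, 1L, 2L), c(4, 1, 1))
  g <- build_glcm(make_qvoi(strip, 2), c(1, 0, 0))
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  g_rev <- build_glcm(make_qvoi(strip, 2), c(-1, 0, 0))
  expect_equal(g_rev$p, g$p)

  const <- make_qvoi(array(1L, c(3, 3, 2)), 3)
  gc <- build_glcm(const, c(1, 0, 0))
  expect_equal(gc$p[1, 1], 1)
  expect_equal(sum(gc$p), 1)

  # no valid pairs: isolated voxel
  lone <- array(0L, c(3, 3, 1)); lone[2, 2, 1] <- 1L
  g0 <- build_glcm(make_qvoi(lone, 2), c(1, 0, 0))
  expect_equal(g0$pair_count, 0)
  expect_error(glcm_features(g0), "no valid pairs")
})

test_that("closed-form 2x2 feature values are exact", {
  g_anti <- make_glcm(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  f <- glcm_features(g_anti)
  expect_equal(unname(f["Dissimilarity"]), 1)
  expect_equal(unname(f["InverseVariance"]), 1)
  expect_equal(unname(f["Autocorrelation"]), 2)
  expect_equal(unname(f["Correlation"]), -1)

  g_diag <- make_glcm(diag(2) / 2)
  f2 <- glcm_features(g_diag)
  expect_equal(unname(f2["Energy"]), 0.5)
  expect_equal(unname(f2["Correlation"]), 1)
  expect_equal(unname(f2["ClusterShade"]), 0)

  g_const <- make_glcm(matrix(c(1, 0, 0, 0), 2, 2))
  f3 <- glcm_features(g_const)
  expect_equal(unname(f3[c("Dissimilarity", "Contrast", "Entropy")]), c(0, 0, 0))
  expect_equal(unname(f3["Energy"]), 1)
  expect_true(is.na(f3["Correlation"]))
})

test_that("Energy and Entropy hit their analytic extremes", {
  # Energy = 1 iff a single nonzero cell
  single <- matrix(0, 4, 4); single[2, 2] <- 1
  expect_equal(unname(glcm_features(make_glcm(single))["Energy"]), 1)
  # k equiprobable cells (symmetric arrangement): Entropy = ln k
  p <- matrix(0, 4, 4); p[1, 1] <- p[2, 2] <- p[3, 3] <- p[4, 4] <- 0.25
  expect_equal(unname(glcm_features(make_glcm(p))["Entropy"]), log(4))
  expect_lt(unname(glcm_features(make_glcm(p))["Energy"]), 1)
})

test_that("features are invariant to flipping along the offset axis", {
  set.seed(31)
  for (rep in 1:5) {
    q <- random_qvoi(c(7, 6, 3), 4)
    if (build_glcm(q, c(1, 0, 0))$pair_count == 0) next
    flipped <- make_qvoi(q$levels[dim(q$levels)[1]:1, , , drop = FALSE], 4)
    f1 <- glcm_features(build_glcm(q, c(1, 0, 0)))
    f2 <- glcm_features(build_glcm(flipped, c(1, 0, 0)))
    expect_equal(f1, f2, tolerance = 1e-12)
  }
})

test_that("monotone intensity transforms leave extracted features unchanged", {
  set.seed(13)
  sp <- c(0.45, 0.45, 2)
  v <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  m <- voi_mask(array(TRUE, dim(v)), sp)
  vol1 <- image_volume(v, sp)
  vol2 <- image_volume(2 * v + 5, sp)   # increasing affine map
  f1 <- extract_voi_features(vol1, m, n_levels = 8, min_voxels = 10)
  f2 <- extract_voi_features(vol2, m, n_levels = 8, min_voxels = 10)
  expect_equal(f1$features, f2$features, tolerance = 1e-12)
})

test_that("VOI extraction honors eligibility, aggregation and isotropy", {
  sp <- c(0.45, 0.45, 2)
  set.seed(5)
  v <- array(rnorm(10 * 10 * 4), c(10, 10, 4))
  vol <- image_volume(v, sp)

  m99 <- array(FALSE, dim(v)); m99[seq_len(99)] <- TRUE
  fv <- extract_voi_features(vol, voi_mask(m99, sp))
  expect_false(fv$eligible)
  expect_match(fv$reason, "99")
  expect_true(all(is.na(fv$features)))

  mask <- voi_mask(array(TRUE, dim(v)), sp)
  one <- extract_voi_features(vol, mask, n_levels = 8,
                              offsets = list(c(1L, 0L, 0L)), min_voxels = 10)
  direct <- glcm_features(build_glcm(quantize(vol, mask, 8), c(1, 0, 0)))
  expect_equal(one$features, direct, tolerance = 1e-12)

  # isotropic random field: the 4 in-plane directions agree within 10% of the
  # mean (skewed intensities keep the feature means away from 0; the features
  # that are structurally ~0 under spatial independence, Correlation and
  # IMC2, are held to an absolute band instead — a relative tolerance is
  # meaningless at zero)
  set.seed(99)
  big <- image_volume(array(exp(0.7 * rnorm(40 * 40 * 6)), c(40, 40, 6)),
                      c(1, 1, 1))
  bmask <- voi_mask(array(TRUE, c(40, 40, 6)), c(1, 1, 1))
  q <- quantize(big, bmask, 8)
  per_dir <- vapply(glcm_offsets("inplane4"),
                    function(d) glcm_features(build_glcm(q, d)),
                    numeric(10))
  mu <- rowMeans(per_dir)
  spread <- apply(per_dir, 1, function(x) diff(range(x)))
  big_mean <- abs(mu) > 0.05
  expect_true(all(spread[big_mean] / abs(mu[big_mean]) < 0.10))
  expect_true(all(spread[!big_mean] < 0.02))
})
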