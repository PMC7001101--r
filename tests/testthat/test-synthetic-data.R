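test_that("phantom VOIs hit their target volume and are deterministic", {
  p <- texture_class_params(100, 20, c(0.5, 0.5, 1))
  sp <- c(0.45, 0.45, 2)
  ph <- generate_textured_voi(p, 4.19, sp, seed = 1)
  target_n <- 4190 / prod(sp)
  expect_lt(abs(sum(ph$mask$voxels) - target_n) / target_n, 0.05)
  expect_identical(dim(ph$volume$voxels), dim(ph$mask$voxels))

  ph2 <- generate_textured_voi(p, 4.19, sp, seed = 1)
  expect_identical(ph$volume$voxels, ph2$volume$voxels)
  ph3 <- generate_textured_voi(p, 4.19, sp, seed = 2)
  inm <- ph$mask$voxels
  expect_gt(mean(ph$volume$voxels[inm] != ph3$volume$voxels[inm]), 0.5)
})

test_that("zero-variance texture gives a constant VOI; sub-voxel targets error", {
  p0 <- texture_class_params(100, 0)
  ph <- generate_textured_voi(p0, 0.05, c(0.45, 0.45, 2), seed = 3)
  expect_true(all(ph$volume$voxels[ph$mask$voxels] == 100))
  expect_error(
    generate_textured_voi(p0, 1e-7, c(0.45, 0.45, 2), seed = 1),
    "voxel")
})

test_that("requested in-mask mean/sd and correlation structure materialize", {
  p <- texture_class_params(50, 10, c(2, 2, 4))
  ph <- generate_textured_voi(p, 2, c(0.45, 0.45, 2), seed = 11)
  v <- ph$volume$voxels[ph$mask$voxels]
  expect_equal(mean(v), 50, tolerance = 1e-6)
  expect_equal(sd(v), 10, tolerance = 1e-6)
  # smoothing induces strong neighbour correlation relative to white noise
  pw <- texture_class_params(50, 10, 0)
  phw <- generate_textured_voi(pw, 2, c(0.45, 0.45, 2), seed = 11)
  lag_cor <- function(a) {
    d <- dim(a)
    cor(as.vector(a[-d[1], , ]), as.vector(a[-1, , ]))
  }
  expect_gt(lag_cor(ph$volume$voxels), 0.8)
  expect_lt(abs(lag_cor(phw$volume$voxels)), 0.1)
})

test_that("the DWI simulator follows the mono-exponential signal model", {
  adc <- image_volume(array(1.0e-3, c(2, 2, 1)), c(0.45, 0.45, 2), "ADC")
  ser <- generate_dwi_from_adc(adc, s0 = 1000, b_values = c(0, 800))
  expect_equal(ser$volumes[[2]]$voxels[1, 1, 1], 1000 * exp(-0.8),
               tolerance = 1e-12)
  zero <- image_volume(array(0, c(2, 2, 1)), c(0.45, 0.45, 2), "ADC")
  zser <- generate_dwi_from_adc(zero, s0 = 1000, b_values = c(0, 300, 800))
  for (v in zser$volumes) expect_true(all(v$voxels == 1000))

  expect_error(generate_dwi_from_adc(adc, 1000, noise_sd = -1), "noise_sd")

  big <- image_volume(array(1.0e-3, c(100, 100, 1)), c(0.45, 0.45, 2), "ADC")
  noisy <- generate_dwi_from_adc(big, s0 = 1000, b_values = c(0, 800),
                                 noise_sd = 20, seed = 4)
  resid <- noisy$volumes[[1]]$voxels - 1000
  expect_lt(abs(sd(resid) - 20) / 20, 0.05)
})

test_that("cohort outcome prevalence matches the generating logistic model", {
  spec <- cohort_generator_spec(
    n_patients = 5000,
    outcome_coefficients = c("(Intercept)" = qlogis(0.1)),
    seed = 21)
  gen <- generate_cohort(spec)
  rate <- mean(gen$cohort$recurrence, na.rm = TRUE)
  # LLN at n = 5000: 2 binomial sd of 0.1 is ~0.0085
  expect_lt(abs(rate - 0.10), 0.02)
})

test_that("arm split, volume dichotomy and determinism hold by construction", {
  thr <- sphere_volume_cm3(2)
  highs <- vapply(1:30, function(s) {
    gen <- generate_cohort(cohort_generator_spec(seed = s))
    expect_true(all(gen$cohort$volume_cm3[gen$cohort$arm == "low"] <= thr))
    expect_true(all(gen$cohort$volume_cm3[gen$cohort$arm == "high"] > thr))
    sum(gen$cohort$arm == "high")
  }, numeric(1))
  # E[high] = 125 * 46/125 = 46; se of the mean over 30 draws ~ 1
  expect_lt(abs(mean(highs) - 46), 4)

  g1 <- generate_cohort(cohort_generator_spec(seed = 5))
  g2 <- generate_cohort(cohort_generator_spec(seed = 5))
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$features, g2$features)
})

test_that("unknown outcome coefficient terms are rejected with the valid list", {
  expect_error(
    cohort_generator_spec(outcome_coefficients = c(NotAFeature = 1)),
    "NotAFeature.*valid terms")
})

test_that("a strong planted texture effect is recoverable from the outcome", {
  spec <- cohort_generator_spec(
    n_patients = 2000,
    outcome_coefficients = c("(Intercept)" = qlogis(0.1),
                             ADC_Dissimilarity = 2.0),
    seed = 31)
  gen <- generate_cohort(spec)
  wide <- features_wide(gen$features)
  d <- merge(gen$cohort, wide, by = "patient_id")
  d <- d[!is.na(d$recurrence), ]
  lp <- 2.0 * scale(d$ADC_Dissimilarity)[, 1]
  expect_gt(roc_auc(lp, d$recurrence, with_threshold = FALSE)$auc, 0.8)
})

test_that("phantom-backed cohorts run the real extraction pipeline", {
  # modest high-arm volumes keep the fixture quick; both arms must appear
  spec <- cohort_generator_spec(
    n_patients = 8, fraction_high_volume = 0.5,
    volume_distributions = list(low = list(meanlog = 0, sdlog = 0.3),
                                high = list(meanlog = log(6), sdlog = 0.15)),
    seed = 13)
  gen <- generate_cohort(spec, with_phantoms = TRUE)
  expect_setequal(unique(gen$cohort$arm), c("low", "high"))
  expect_equal(nrow(gen$features), 16)  # 8 patients x 2 modalities
  expect_true(all(gen$features$voxel_count >= 100))
  expect_false(anyNA(gen$features[, texture_feature_names()]))
  # high-volume arm gets coarser texture (longer correlation length) =>
  # lower dissimilarity after quantization
  wide <- features_wide(gen$features)
  d <- merge(gen$cohort, wide, by = "patient_id")
  expect_gt(mean(d$T2W_Dissimilarity[d$arm == "low"]),
            mean(d$T2W_Dissimilarity[d$arm == "high"]))
})

test_that("noiseless DWI round-trips through the ADC fitter", {
  set.seed(17)
  adc_vals <- array(runif(1000, 2e-4, 2.5e-3), c(10, 10, 10))
  adc <- image_volume(adc_vals, c(0.45, 0.45, 2), "ADC")
  ser <- generate_dwi_from_adc(adc, s0 = 1200)
  fit <- fit_adc_map(ser)
  expect_lt(max(abs(fit$voxels - adc_vals)), 1e-12)
})
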