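# Synthetic phantoms and cohorts.
#
# No imaging data accompany the study this pipeline re-implements, so the
# generator produces the inputs the analysis assumes: correlated-Gaussian
# textured ellipsoidal tumours on anisotropic grids, mono-exponential DWI
# series, and a cohort whose recurrence outcome follows a known logistic
# model on texture + clinical covariates.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Texture class parameters for phantom tumours
#'
#' Describes one textural phenotype: a stationary correlated Gaussian field
#' with a given mean and standard deviation and a per-axis correlation length
#' in mm, plus an optional additive periodic component (a cheap way to raise
#' Energy, i.e. textural uniformity, in one class).
#'
#' @param mean_intensity mean in-mask intensity (arbitrary units).
#' @param sd_intensity in-mask standard deviation of the stochastic part
#'   (>= 0; 0 gives a constant VOI).
#' @param correlation_length_mm per-axis Gaussian smoothing scale in mm
#'   (length 1 or 3; 0 gives white noise).
#' @param periodic_amplitude amplitude of an optional sinusoid along x.
#' @param periodic_period_mm its period in mm.
#' @return Object of class `texture_class_params`.
#' @export
texture_class_params <- function(mean_intensity, sd_intensity,
                                 correlation_length_mm = 0,
                                 periodic_amplitude = 0,
                                 periodic_period_mm = Inf) {
  if (sd_intensity < 0) stop("`sd_intensity` must be >= 0", call. = FALSE)
  cl <- rep(as.numeric(correlation_length_mm), length.out = 3)
  if (any(cl < 0)) stop("`correlation_length_mm` must be >= 0 per axis", call. = FALSE)
  if (periodic_amplitude < 0) stop("`periodic_amplitude` must be >= 0", call. = FALSE)
  if (periodic_amplitude > 0 && !(periodic_period_mm > 0))
    stop("`periodic_period_mm` must be positive when an amplitude is set", call. = FALSE)
  structure(list(mean_intensity = mean_intensity, sd_intensity = sd_intensity,
                 correlation_length_mm = cl,
                 periodic_amplitude = periodic_amplitude,
                 periodic_period_mm = periodic_period_mm),
            class = "texture_class_params")
}

# Circular Gaussian smoothing of a white-noise array: circular convolution of
# stationary white noise is itself stationary with the requested kernel, so
# no padding is needed.
smooth_field <- function(noise, sigma_vox) {
  dims <- dim(noise)
  if (all(sigma_vox <= 0)) return(noise)
  kern <- 1
  for (ax in 1:3) {
    n <- dims[ax]
    x <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
    k <- if (sigma_vox[ax] > 0) exp(-x^2 / (2 * sigma_vox[ax]^2)) else as.numeric(x == 0)
    k <- k / sum(k)
    shape <- c(1, 1, 1); shape[ax] <- n
    kern <- outer_general(kern, array(k, dim = shape))
  }
  Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) / prod(dims)
}

outer_general <- function(a, b) {
  if (identical(a, 1)) return(b)
  da <- dim(a); db <- dim(b)
  out <- array(0, pmax(da, db))
  # both arrays broadcast along singleton axes
  av <- array(a, pmax(da, db))  # valid because singleton axes recycle in order
  # recycle b manually: permute so its non-singleton axis varies correctly
  idx <- arrayInd(seq_len(prod(dim(out))), dim(out))
  bv <- b[cbind(ifelse(db[1] == 1, 1, idx[, 1]),
                ifelse(db[2] == 1, 1, idx[, 2]),
                ifelse(db[3] == 1, 1, idx[, 3]))]
  array(as.vector(av) * bv, dim = dim(out))
}

#' Generate a textured ellipsoidal phantom tumour
#'
#' Builds an ellipsoidal VOI (axis ratio 1 : 1 : 0.7 by default) whose
#' rasterized volume matches `target_volume_cm3` to within 5% (subject to the
#' 1-voxel minimum), then fills it with a stationary correlated Gaussian
#' field: white noise is smoothed by a per-axis Gaussian kernel whose width
#' in voxels is the correlation length divided by the voxel spacing, then
#' rescaled in-mask to the requested mean and standard deviation. Identical
#' `params` + `seed` give bit-identical output.
#'
#' @param params a [texture_class_params()].
#' @param target_volume_cm3 target VOI volume in cm^3 (> 0).
#' @param spacing_mm voxel spacing in mm.
#' @param seed integer RNG seed (mandatory: phantoms are provenance-tracked).
#' @param modality modality tag for the generated volume.
#' @param axis_ratio_z through-plane semi-axis relative to in-plane (0.7).
#' @return `list(volume = image_volume, mask = voi_mask)`.
#' @export
generate_textured_voi <- function(params, target_volume_cm3, spacing_mm, seed,
                                  modality = "T2W", axis_ratio_z = 0.7) {
  stopifnot(inherits(params, "texture_class_params"))
  spacing_mm <- as.numeric(spacing_mm)
  if (!(target_volume_cm3 > 0)) stop("`target_volume_cm3` must be > 0", call. = FALSE)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers", call. = FALSE)
  voxel_mm3 <- prod(spacing_mm)
  target_mm3 <- target_volume_cm3 * 1000
  if (target_mm3 < voxel_mm3)
    stop(sprintf("target volume %.4g mm^3 is smaller than one voxel (%.4g mm^3)",
                 target_mm3, voxel_mm3), call. = FALSE)
  target_n <- max(1L, round(target_mm3 / voxel_mm3))

  # ideal in-plane semi-axis a from (4/3) pi a^2 (ratio a) = target
  a0 <- (target_mm3 * 3 / (4 * pi * axis_ratio_z))^(1 / 3)
  # refine the scale so the rasterized count lands nearest the target count
  scales <- seq(0.85, 1.15, length.out = 121)
  best <- NULL; best_err <- Inf
  for (s in scales) {
    m <- rasterize_ellipsoid(a0 * s * c(1, 1, axis_ratio_z), spacing_mm)
    err <- abs(sum(m$voxels) - target_n)
    if (err < best_err) { best <- m; best_err <- err }
    if (err == 0) break
  }
  mask <- best

  dims <- dim(mask$voxels)
  vox <- with_seed(seed, {
    noise <- array(stats::rnorm(prod(dims)), dim = dims)
    field <- smooth_field(noise, params$correlation_length_mm / spacing_mm)
    field
  })
  inm <- mask$voxels
  if (params$sd_intensity > 0 && sum(inm) > 1) {
    mu <- mean(vox[inm]); sdv <- stats::sd(vox[inm])
    if (sdv > 0) vox <- (vox - mu) / sdv * params$sd_intensity
    vox <- vox + params$mean_intensity
  } else {
    vox[] <- params$mean_intensity
  }
  if (params$periodic_amplitude > 0) {
    x_mm <- (seq_len(dims[1]) - 1) * spacing_mm[1]
    wave <- params$periodic_amplitude * sin(2 * pi * x_mm / params$periodic_period_mm)
    vox <- vox + array(wave, dim = dims)
  }
  list(volume = image_volume(vox, spacing_mm, modality = modality),
       mask = mask)
}

#' Simulate a DWI series from an ADC map
#'
#' Per voxel the signal at b is `s0 * exp(-b * ADC)` plus Gaussian noise of
#' standard deviation `noise_sd` (optionally Rician, i.e. the magnitude of a
#' complex signal with independent Gaussian noise on both channels).
#'
#' @param adc_map [image_volume()] of non-negative ADC values (mm^2/s).
#' @param s0 signal at b = 0.
#' @param b_values b-values in s/mm^2 (default the acquisition scheme
#'   0, 100, 300, 500, 800).
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @param rician use Rician magnitude noise instead of additive Gaussian.
#' @return A [dwi_series()].
#' @export
generate_dwi_from_adc <- function(adc_map, s0, b_values = c(0, 100, 300, 500, 800),
                                  noise_sd = 0, seed = NULL, rician = FALSE) {
  stopifnot(inherits(adc_map, "image_volume"))
  if (any(adc_map$voxels < 0)) stop("ADC values must be >= 0", call. = FALSE)
  if (length(b_values) < 1L || any(b_values < 0))
    stop("`b_values` must be non-empty and non-negative", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (noise_sd > 0 && is.null(seed))
    stop("`seed` is required when noise is simulated", call. = FALSE)
  dims <- dim(adc_map$voxels)
  gen <- function() {
    lapply(b_values, function(b) {
      sig <- s0 * exp(-b * adc_map$voxels)
      if (noise_sd > 0) {
        if (rician) {
          n1 <- array(stats::rnorm(prod(dims), sd = noise_sd), dims)
          n2 <- array(stats::rnorm(prod(dims), sd = noise_sd), dims)
          sig <- sqrt((sig + n1)^2 + n2^2)
        } else {
          sig <- sig + array(stats::rnorm(prod(dims), sd = noise_sd), dims)
        }
      }
      image_volume(sig, adc_map$spacing_mm, modality = paste0("DWI-b", b))
    })
  }
  vols <- if (noise_sd > 0) with_seed(seed, gen()) else gen()
  dwi_series(vols, b_values)
}

# Per-arm sampling distributions of the texture features, centred on the
# reported low-/high-volume medians with spread IQR/1.349 (normal-equivalent
# sd), truncated to each feature's valid range.
feature_arm_distributions <- function() {
  f <- function(feature, modality, med_lo, iqr_lo, med_hi, iqr_hi, lower, upper)
    data.frame(feature = feature, modality = modality, med_lo = med_lo,
               iqr_lo = iqr_lo, med_hi = med_hi, iqr_hi = iqr_hi,
               lower = lower, upper = upper, stringsAsFactors = FALSE)
  rbind(
    f("Dissimilarity", "ADC", 0.64, 0.28, 0.35, 0.17, 0, Inf),
    f("Dissimilarity", "T2W", 0.49, 0.32, 0.25, 0.12, 0, Inf),
    f("Energy", "ADC", 0.15, 0.11, 0.30, 0.21, 1e-6, 1),
    f("Energy", "T2W", 0.20, 0.13, 0.34, 0.20, 1e-6, 1),
    f("InverseVariance", "ADC", 0.41, 0.08, 0.29, 0.13, 0, Inf),
    f("InverseVariance", "T2W", 0.38, 0.12, 0.23, 0.10, 0, Inf),
    f("ClusterProminence", "ADC", 29.33, 40.77, 10.52, 10.11, 0, Inf),
    f("ClusterProminence", "T2W", 22.66, 24.14, 8.03, 6.50, 0, Inf),
    f("ClusterShade", "ADC", 2.82, 3.62, 1.26, 1.42, -Inf, Inf),
    f("ClusterShade", "T2W", 2.29, 2.28, 1.18, 1.30, -Inf, Inf),
    f("Autocorrelation", "ADC", 11.41, 5.68, 9.13, 4.64, 0, Inf),
    f("Autocorrelation", "T2W", 11.65, 8.69, 6.08, 3.64, 0, Inf),
    f("InformationalMeasureCorrelation2", "ADC", 0.63, 0.21, 0.54, 0.07, 0, 1),
    f("InformationalMeasureCorrelation2", "T2W", 0.67, 0.16, 0.68, 0.22, 0, 1),
    f("Correlation", "ADC", 0.44, 0.18, 0.47, 0.07, -1, 1),
    f("Correlation", "T2W", 0.55, 0.23, 0.62, 0.26, -1, 1)
  )
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    tries <- tries + 1L
  }
  pmin(pmax(x, lower), upper)
}

cohort_coefficient_terms <- function() {
  feats <- feature_arm_distributions()
  c("(Intercept)",
    paste(feats$modality, feats$feature, sep = "_"),
    "volume_cm3", "depth_mm", "lvsi", "grade3", "nodes", "parametrium",
    "type_adeno", "adjuvant")
}

#' Cohort generator specification
#'
#' Defaults emulate the published cohort structure: 125 patients, 46/125
#' high-volume; low-arm volumes log-normal with mean 1.3 and sd 1.2 cm^3
#' truncated at the 4.19 cm^3 trachelectomy threshold, high-arm mean 15.3 and
#' sd 11.7 cm^3 truncated above it; clinical covariate prevalences from the
#' published demographics; texture features drawn per arm from distributions
#' centred on the published medians. The recurrence outcome is Bernoulli on a
#' logistic linear predictor over `outcome_coefficients`; continuous terms
#' enter standardized (z-scored within the cohort), binary terms enter 0/1.
#'
#' @param n_patients cohort size.
#' @param fraction_high_volume proportion above the volume threshold.
#' @param volume_distributions list with `low`/`high`, each
#'   `list(meanlog, sdlog)` for the log-normal volume (cm^3) of that arm.
#' @param outcome_coefficients named numeric map term -> logistic
#'   coefficient; valid terms are `"(Intercept)"`, modality-prefixed feature
#'   names, and the clinical covariates.
#' @param clinical_covariate_prevalences named list of proportions.
#' @param threshold_cm3 the volume dichotomy (4.19 cm^3).
#' @param seed integer seed.
#' @return Object of class `cohort_generator_spec`.
#' @export
cohort_generator_spec <- function(
    n_patients = 125L,
    fraction_high_volume = 46 / 125,
    volume_distributions = list(
      low = list(meanlog = -0.046, sdlog = 0.785),
      high = list(meanlog = 2.498, sdlog = 0.679)),
    outcome_coefficients = c(
      "(Intercept)" = stats::qlogis(0.10),
      ADC_Dissimilarity = 1.0, ADC_Energy = -0.8,
      volume_cm3 = 0.8, depth_mm = 0.5, lvsi = 0.7),
    clinical_covariate_prevalences = list(
      lvsi = 0.27, grade3 = 0.43, type_adeno = 0.38, nodes = 0.31,
      parametrium = 0.33, adjuvant = 0.23, surgery_low = 0.886,
      surgery_high = 0.152, followup = 68 / 70),
    threshold_cm3 = sphere_volume_cm3(2),
    seed = 1L) {
  if (n_patients < 1L) stop("`n_patients` must be >= 1", call. = FALSE)
  if (fraction_high_volume < 0 || fraction_high_volume > 1)
    stop("`fraction_high_volume` must be in [0, 1]", call. = FALSE)
  prev <- clinical_covariate_prevalences
  if (any(unlist(prev) < 0 | unlist(prev) > 1))
    stop("all covariate prevalences must be in [0, 1]", call. = FALSE)
  bad <- setdiff(names(outcome_coefficients), cohort_coefficient_terms())
  if (length(bad))
    stop(sprintf("unknown outcome coefficient term(s): %s\nvalid terms: %s",
                 paste(bad, collapse = ", "),
                 paste(cohort_coefficient_terms(), collapse = ", ")),
         call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 fraction_high_volume = fraction_high_volume,
                 volume_distributions = volume_distributions,
                 outcome_coefficients = outcome_coefficients,
                 clinical_covariate_prevalences = prev,
                 threshold_cm3 = threshold_cm3,
                 seed = as.integer(seed)),
            class = "cohort_generator_spec")
}

#' Generate a synthetic cohort
#'
#' Draws arm membership, tumour volume (low-arm volumes never exceed the
#' threshold, by construction), clinical covariates, per-arm texture
#' features, and a recurrence outcome that is Bernoulli on the logistic
#' linear predictor defined by the spec's coefficients. With
#' `with_phantoms = TRUE` the texture feature columns are instead produced
#' by running the real extraction pipeline on generated phantom volumes
#' (slow; intended for small demonstration cohorts), using two texture
#' classes that differ in correlation length between the arms.
#'
#' @param spec a [cohort_generator_spec()].
#' @param with_phantoms extract features from generated phantoms instead of
#'   sampling them from the per-arm distributions.
#' @param phantom_params optional `list(low =, high =)` of
#'   [texture_class_params()] used in phantom mode.
#' @return `list(cohort = data.frame, features = data.frame)`: the clinical
#'   cohort table and the long (patient, modality) feature table.
#' @export
generate_cohort <- function(spec, with_phantoms = FALSE, phantom_params = NULL) {
  stopifnot(inherits(spec, "cohort_generator_spec"))
  n <- spec$n_patients
  prev <- spec$clinical_covariate_prevalences
  thr <- spec$threshold_cm3
  with_seed(spec$seed, {
    arm <- ifelse(stats::runif(n) < spec$fraction_high_volume, "high", "low")
    vol <- numeric(n)
    for (i in seq_len(n)) {
      d <- spec$volume_distributions[[arm[i]]]
      repeat {
        v <- stats::rlnorm(1, d$meanlog, d$sdlog)
        if ((arm[i] == "low" && v <= thr) || (arm[i] == "high" && v > thr)) break
      }
      vol[i] <- v
    }
    cohort <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      arm = arm,
      volume_cm3 = vol,
      type_adeno = as.integer(stats::runif(n) < prev$type_adeno),
      grade3 = as.integer(stats::runif(n) < prev$grade3),
      lvsi = as.integer(stats::runif(n) < prev$lvsi),
      depth_mm = pmax(0.5, stats::rnorm(n, 7.1, 4)),
      parametrium = as.integer(stats::runif(n) < prev$parametrium),
      nodes = as.integer(stats::runif(n) < prev$nodes),
      stringsAsFactors = FALSE)
    p_surg <- ifelse(arm == "low", prev$surgery_low, prev$surgery_high)
    cohort$treatment <- ifelse(stats::runif(n) < p_surg, "surgery", "chemoradiation")
    cohort$adjuvant <- ifelse(cohort$treatment == "surgery",
                              as.integer(stats::runif(n) < prev$adjuvant), 0L)
    cohort$followup <- as.integer(stats::runif(n) < prev$followup)

    dists <- feature_arm_distributions()
    feats_wide <- data.frame(patient_id = cohort$patient_id,
                             stringsAsFactors = FALSE)
    if (with_phantoms) {
      if (is.null(phantom_params)) phantom_params <- default_phantom_params()
      rows <- vector("list", 2L * n)
      # per-patient sub-seeds, kept inside the 32-bit integer range
      sub_seed <- function(i) as.integer((as.numeric(spec$seed) * 1000 + i) %%
                                           .Machine$integer.max)
      for (i in seq_len(n)) {
        cls <- phantom_params[[arm[i]]]
        ph_t2 <- generate_textured_voi(cls$T2W, vol[i], c(0.35, 0.35, 2),
                                       seed = sub_seed(i), modality = "T2W")
        ph_adc <- generate_textured_voi(cls$ADC, vol[i], c(0.45, 0.45, 2),
                                        seed = sub_seed(n + i),
                                        modality = "ADC")
        fv_t2 <- extract_voi_features(ph_t2$volume, ph_t2$mask)
        fv_adc <- extract_voi_features(ph_adc$volume, ph_adc$mask)
        rows[[2 * i - 1]] <- voi_features_row(fv_t2, cohort$patient_id[i], "T2W")
        rows[[2 * i]] <- voi_features_row(fv_adc, cohort$patient_id[i], "ADC")
      }
      features <- do.call(rbind, rows)
      fw <- features_wide(features)
      feats_wide <- fw
    } else {
      vc <- list()
      for (r in seq_len(nrow(dists))) {
        d <- dists[r, ]
        col <- paste(d$modality, d$feature, sep = "_")
        x <- numeric(n)
        lo_idx <- arm == "low"
        x[lo_idx] <- rtrunc_norm(sum(lo_idx), d$med_lo, d$iqr_lo / 1.349,
                                 d$lower, d$upper)
        x[!lo_idx] <- rtrunc_norm(sum(!lo_idx), d$med_hi, d$iqr_hi / 1.349,
                                  d$lower, d$upper)
        feats_wide[[col]] <- x
        vc[[col]] <- x
      }
      features <- sampled_features_long(cohort, feats_wide)
    }
    cohort$recurrence <- draw_recurrence(cohort, feats_wide,
                                         spec$outcome_coefficients)
    cohort$recurrence[cohort$followup == 0L] <- NA_integer_
    list(cohort = cohort, features = features)
  })
}

default_phantom_params <- function() {
  list(low = list(T2W = texture_class_params(100, 20, c(0.4, 0.4, 0.8)),
                  ADC = texture_class_params(1.1e-3, 2.5e-4, c(0.5, 0.5, 1))),
       high = list(T2W = texture_class_params(100, 20, c(1.2, 1.2, 2.4)),
                   ADC = texture_class_params(1.0e-3, 2.5e-4, c(1.5, 1.5, 3))))
}

sampled_features_long <- function(cohort, feats_wide) {
  rows <- list()
  spacing <- list(T2W = c(0.35, 0.35, 2), ADC = c(0.45, 0.45, 2))
  for (mod in c("ADC", "T2W")) {
    cols <- paste(mod, texture_feature_names(), sep = "_")
    block <- data.frame(patient_id = cohort$patient_id, modality = mod,
                        stringsAsFactors = FALSE)
    for (fn in texture_feature_names()) {
      col <- paste(mod, fn, sep = "_")
      block[[fn]] <- if (col %in% names(feats_wide)) feats_wide[[col]] else NA_real_
    }
    # Contrast/Entropy track Dissimilarity/Energy tightly in real data (they
    # are the pruned-away near-duplicates); emulate that coupling.
    block$Contrast <- block$Dissimilarity * 2.2 +
      stats::rnorm(nrow(block), 0, 0.04 * stats::sd(block$Dissimilarity) + 1e-9)
    block$Entropy <- pmax(0, 2.5 - 2.0 * block$Energy +
      stats::rnorm(nrow(block), 0, 0.04 * stats::sd(block$Energy) + 1e-9))
    vox_mm3 <- prod(spacing[[mod]])
    block$voxel_count <- pmax(1L, as.integer(round(cohort$volume_cm3 * 1000 / vox_mm3)))
    block$volume_cm3 <- cohort$volume_cm3
    rows[[mod]] <- block[, feature_table_columns()]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

draw_recurrence <- function(cohort, feats_wide, coefs) {
  lp <- rep(0, nrow(cohort))
  for (term in names(coefs)) {
    if (term == "(Intercept)") { lp <- lp + coefs[[term]]; next }
    x <- if (term %in% names(feats_wide)) feats_wide[[term]] else cohort[[term]]
    if (is.null(x)) stop(sprintf("coefficient term '%s' not found", term), call. = FALSE)
    if (length(unique(x)) > 2L) {
      s <- stats::sd(x)
      x <- if (s > 0) (x - mean(x)) / s else x * 0
    }
    lp <- lp + coefs[[term]] * x
  }
  as.integer(stats::runif(nrow(cohort)) < stats::plogis(lp))
}

#' Write a generated cohort to CSV
#'
#' @param cohort cohort `data.frame` from [generate_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path CSV with at least patient_id, volume_cm3, treatment,
#'   adjuvant, followup, recurrence plus clinical covariates.
#' @return `data.frame`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cohort file does not exist: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("patient_id", "volume_cm3", "treatment", "adjuvant", "followup",
            "recurrence")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("cohort table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df
}
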