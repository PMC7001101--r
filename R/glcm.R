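#' Quantize a masked volume to grey levels
#'
#' Equal-width binning of the in-mask intensity range into `n_levels` levels:
#' an in-mask value v maps to `floor((v - min) / (max - min) * Ng) + 1`, with
#' `v = max` assigned level `Ng`. Voxels outside the mask are exactly 0. A
#' constant VOI maps entirely to level 1. Because the bins are set by the
#' in-mask min and max, any increasing affine transform of the intensities
#' leaves the quantization unchanged.
#'
#' @param volume an [image_volume()].
#' @param mask a [voi_mask()] on the same grid.
#' @param n_levels number of grey levels Ng >= 2 (default 32).
#' @return Object of class `quantized_voi`: list with `levels` (integer 3D
#'   grid, 1..Ng inside the mask, 0 outside), `n_levels`, `range` (in-mask
#'   min/max used), and `spacing_mm`.
#' @export
quantize <- function(volume, mask, n_levels = 32L) {
  check_mask_matches(volume, mask)
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("`n_levels` must be >= 2", call. = FALSE)
  inmask <- mask$voxels
  if (!any(inmask)) stop("mask is empty; nothing to quantize", call. = FALSE)
  v <- volume$voxels[inmask]
  lo <- min(v); hi <- max(v)
  lev <- array(0L, dim = dim(volume$voxels))
  if (hi == lo) {
    lev[inmask] <- 1L
  } else {
    q <- floor((v - lo) / (hi - lo) * n_levels) + 1L
    q[q > n_levels] <- n_levels
    lev[inmask] <- as.integer(q)
  }
  structure(list(levels = lev, n_levels = n_levels, range = c(lo, hi),
                 spacing_mm = volume$spacing_mm),
            class = "quantized_voi")
}

#' Standard GLCM displacement sets
#'
#' `"inplane4"` gives the 4 unique in-plane unit directions (0 deg, 45 deg,
#' 90 deg, 135 deg), pooled over all slices; through-plane co-occurrence is
#' deliberately excluded by default because slices are ~6x thicker than the
#' in-plane voxel size. `"full13"` gives the 13 unique 3D directions at
#' Chebyshev distance 1.
#'
#' @param mode `"inplane4"` or `"full13"`.
#' @return List of integer length-3 displacement vectors.
#' @export
glcm_offsets <- function(mode = c("inplane4", "full13")) {
  mode <- match.arg(mode)
  inplane <- list(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L), c(-1L, 1L, 0L))
  if (mode == "inplane4") return(inplane)
  thru <- list(c(0L, 0L, 1L),
               c(1L, 0L, 1L), c(-1L, 0L, 1L), c(0L, 1L, 1L), c(0L, -1L, 1L),
               c(1L, 1L, 1L), c(-1L, 1L, 1L), c(1L, -1L, 1L), c(-1L, -1L, 1L))
  c(inplane, thru)
}

#' Build a symmetric grey-level co-occurrence matrix
#'
#' Counts ordered voxel pairs (a, a + d) with both voxels inside the mask,
#' symmetrizes by also counting the reverse pair, and normalizes by the total
#' pair count. If the offset yields no valid in-mask pair, the GLCM is
#' returned with `pair_count = 0` and features computed from it are an error.
#'
#' @param qvoi a [quantize()]d VOI.
#' @param offset integer length-3 voxel displacement, not all zero.
#' @return Object of class `glcm`: list with `p` (Ng x Ng joint probability
#'   matrix), `offset`, `pair_count` (symmetrized count) and `n_levels`.
#' @export
build_glcm <- function(qvoi, offset) {
  stopifnot(inherits(qvoi, "quantized_voi"))
  d <- as.integer(offset)
  if (length(d) != 3L || all(d == 0L))
    stop("`offset` must be a non-zero integer 3-vector", call. = FALSE)
  L <- qvoi$levels
  ng <- qvoi$n_levels
  dims <- dim(L)
  src <- lapply(1:3, function(ax) {
    lo <- max(1L, 1L - d[ax]); hi <- min(dims[ax], dims[ax] - d[ax])
    if (lo > hi) integer(0) else lo:hi
  })
  counts <- matrix(0, ng, ng)
  if (all(lengths(src) > 0)) {
    a <- L[src[[1]], src[[2]], src[[3]]]
    b <- L[src[[1]] + d[1], src[[2]] + d[2], src[[3]] + d[3]]
    keep <- a > 0L & b > 0L
    if (any(keep)) {
      tab <- tabulate((a[keep] - 1L) * ng + b[keep], nbins = ng * ng)
      counts <- matrix(tab, ng, ng, byrow = TRUE)
      counts <- counts + t(counts)
    }
  }
  total <- sum(counts)
  p <- if (total > 0) counts / total else counts
  structure(list(p = p, offset = d, pair_count = as.integer(total),
                 n_levels = ng),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> Ng=%d  offset (%s)  %d symmetrized pairs\n",
              x$n_levels, paste(x$offset, collapse = ","), x$pair_count))
  invisible(x)
}

#' Haralick texture features of a GLCM
#'
#' With joint probabilities p(i, j) over level indices i, j in 1..Ng,
#' marginals px, py, marginal means mu_x, mu_y and standard deviations
#' sigma_x, sigma_y:
#' \describe{
#'   \item{Contrast}{sum (i - j)^2 p}
#'   \item{Dissimilarity}{sum |i - j| p}
#'   \item{Energy}{sum p^2 (angular second moment; 1 iff a single cell)}
#'   \item{Entropy}{-sum p ln p, with 0 ln 0 := 0 (natural log)}
#'   \item{InverseVariance}{sum over i != j of p / (i - j)^2}
#'   \item{Correlation}{sum (i - mu_x)(j - mu_y) p / (sigma_x sigma_y)}
#'   \item{Autocorrelation}{sum i j p}
#'   \item{ClusterShade}{sum (i + j - mu_x - mu_y)^3 p}
#'   \item{ClusterProminence}{sum (i + j - mu_x - mu_y)^4 p}
#'   \item{InformationalMeasureCorrelation2}{sqrt(1 - exp(-2 (HXY2 - HXY)))
#'     where HXY is the Entropy and HXY2 = -sum px(i) py(j) ln(px(i) py(j))}
#' }
#' For a constant VOI sigma_x sigma_y = 0 and Correlation is undefined; it is
#' returned as `NA` rather than a fabricated value.
#'
#' @param g a [build_glcm()] result with `pair_count > 0`.
#' @return Named numeric vector over [texture_feature_names()].
#' @export
glcm_features <- function(g) {
  stopifnot(inherits(g, "glcm"))
  if (g$pair_count <= 0)
    stop("GLCM has no valid pairs for its offset; features are undefined",
         call. = FALSE)
  p <- g$p
  ng <- g$n_levels
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(seq_len(ng) * px)
  mu_y <- sum(seq_len(ng) * py)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))

  contrast <- sum((i - j)^2 * p)
  dissim <- sum(abs(i - j) * p)
  energy <- sum(p^2)
  pos <- p > 0
  entropy <- -sum(p[pos] * log(p[pos]))
  off <- i != j
  inv_var <- sum(p[off] / (i[off] - j[off])^2)
  correlation <- if (sd_x * sd_y > 0)
    sum((i - mu_x) * (j - mu_y) * p) / (sd_x * sd_y) else NA_real_
  autocorr <- sum(i * j * p)
  dev <- i + j - mu_x - mu_y
  shade <- sum(dev^3 * p)
  prominence <- sum(dev^4 * p)
  pxy <- outer(px, py)
  pospxy <- pxy > 0
  hxy2 <- -sum(pxy[pospxy] * log(pxy[pospxy]))
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  c(Dissimilarity = dissim, Contrast = contrast, Energy = energy,
    Entropy = entropy, ClusterProminence = prominence, ClusterShade = shade,
    InverseVariance = inv_var, Correlation = correlation,
    Autocorrelation = autocorr, InformationalMeasureCorrelation2 = imc2)
}

#' Extract the texture feature vector of a VOI
#'
#' Quantizes the masked volume, builds one GLCM per displacement, computes
#' the Haralick features per displacement and aggregates them (default:
#' unweighted mean over displacements, Haralick's rotational averaging; the
#' `"merged"` alternative pools pair counts into one matrix first). VOIs
#' below the voxel-count eligibility minimum (default 100, mirroring the
#' study's exclusion rule for radiomic analysis) produce an explicit
#' ineligibility record, never a silent drop.
#'
#' @param volume an [image_volume()].
#' @param mask a [voi_mask()] on the same grid.
#' @param n_levels grey levels Ng (default 32).
#' @param offsets `"inplane4"`, `"full13"`, or a list of integer 3-vectors.
#' @param aggregation `"mean"` (per-offset features averaged) or `"merged"`
#'   (counts pooled across offsets before features).
#' @param min_voxels eligibility minimum on the VOI voxel count.
#' @return Object of class `voi_features`: list with `eligible`, `features`
#'   (named vector, NA-filled when ineligible), `voxel_count`, `volume_cm3`,
#'   `pair_counts` per offset, and the configuration used.
#' @export
extract_voi_features <- function(volume, mask, n_levels = 32L,
                                 offsets = "inplane4",
                                 aggregation = c("mean", "merged"),
                                 min_voxels = 100L) {
  aggregation <- match.arg(aggregation)
  check_mask_matches(volume, mask)
  if (is.character(offsets)) offsets <- glcm_offsets(offsets)
  nvox <- sum(mask$voxels)
  vol_cm3 <- voi_volume_cm3(mask)
  base <- list(voxel_count = as.integer(nvox), volume_cm3 = vol_cm3,
               n_levels = as.integer(n_levels), aggregation = aggregation,
               min_voxels = as.integer(min_voxels), modality = volume$modality)
  if (nvox < min_voxels) {
    feats <- stats::setNames(rep(NA_real_, length(texture_feature_names())),
                             texture_feature_names())
    return(structure(c(list(eligible = FALSE, features = feats,
                            pair_counts = integer(0),
                            reason = sprintf("VOI has %d voxels, below the eligibility minimum of %d",
                                             nvox, min_voxels)),
                       base), class = "voi_features"))
  }
  q <- quantize(volume, mask, n_levels)
  glcms <- lapply(offsets, function(d) build_glcm(q, d))
  pair_counts <- vapply(glcms, `[[`, integer(1), "pair_count")
  usable <- pair_counts > 0
  if (!any(usable))
    stop("no offset yields any valid in-mask voxel pair; features undefined",
         call. = FALSE)
  if (aggregation == "mean") {
    mat <- vapply(glcms[usable], glcm_features, numeric(length(texture_feature_names())))
    feats <- rowMeans(mat)
  } else {
    tot <- Reduce(`+`, lapply(glcms[usable], function(g) g$p * g$pair_count))
    merged <- structure(list(p = tot / sum(tot), offset = c(0L, 0L, 0L),
                             pair_count = as.integer(sum(pair_counts)),
                             n_levels = q$n_levels), class = "glcm")
    feats <- glcm_features(merged)
  }
  structure(c(list(eligible = TRUE, features = feats, pair_counts = pair_counts),
              base), class = "voi_features")
}

#' @export
print.voi_features <- function(x, ...) {
  if (!x$eligible) {
    cat(sprintf("<voi_features> INELIGIBLE: %s\n", x$reason))
  } else {
    cat(sprintf("<voi_features> %s  %d voxels (%.3g cm^3)  Ng=%d\n",
                x$modality, x$voxel_count, x$volume_cm3, x$n_levels))
    print(round(x$features, 4))
  }
  invisible(x)
}

#' One feature-table row from an extraction result
#'
#' @param fv a [extract_voi_features()] result.
#' @param patient_id patient identifier.
#' @param modality modality label override (defaults to the volume's).
#' @return Single-row `data.frame` in the feature-table schema.
#' @export
voi_features_row <- function(fv, patient_id, modality = fv$modality) {
  stopifnot(inherits(fv, "voi_features"))
  row <- as.data.frame(as.list(fv$features))
  cbind(data.frame(patient_id = patient_id, modality = modality,
                   stringsAsFactors = FALSE),
        row,
        data.frame(voxel_count = fv$voxel_count, volume_cm3 = fv$volume_cm3))
}
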