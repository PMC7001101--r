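#' Multi-b-value diffusion-weighted series
#'
#' @param volumes list of [image_volume()]s on one grid, one per b-value.
#' @param b_values numeric vector of b-values (s/mm^2) in matching order;
#'   at least two distinct values.
#' @return Object of class `dwi_series`.
#' @export
dwi_series <- function(volumes, b_values) {
  b_values <- as.numeric(b_values)
  if (length(volumes) != length(b_values))
    stop("`volumes` and `b_values` lengths differ", call. = FALSE)
  if (length(unique(b_values)) < 2L)
    stop("need at least two distinct b-values", call. = FALSE)
  if (any(b_values < 0)) stop("b-values must be non-negative", call. = FALSE)
  dims <- dim(volumes[[1]]$voxels)
  sp <- volumes[[1]]$spacing_mm
  for (v in volumes) {
    if (!identical(dim(v$voxels), dims) || max(abs(v$spacing_mm - sp)) > 1e-9)
      stop("all DWI volumes must share dimensions and spacing", call. = FALSE)
  }
  structure(list(volumes = volumes, b_values = b_values), class = "dwi_series")
}

#' Fit a mono-exponential ADC map from a DWI series
#'
#' Per voxel, the apparent diffusion coefficient is minus the slope of the
#' ordinary least-squares regression of ln(signal) on b over all usable
#' b-values: S(b) = S0 exp(-b * ADC). The log is undefined for non-positive
#' signals, so those are excluded voxel-wise rather than silently
#' substituted; a voxel with fewer than two usable b-values is marked invalid
#' (NA), and the per-map counts are reported so downstream texture analysis
#' can see how much of the map was affected.
#'
#' @param series a [dwi_series()].
#' @param floor_at_zero clamp negative fitted ADCs to 0 (counted); negative
#'   fits arise from noise at low true diffusivity.
#' @param b_subset optional subset of b-values to use (the full acquisition
#'   is the default and the conventional scanner computation).
#' @return An [image_volume()] with modality `"ADC"` (units mm^2/s), carrying
#'   an `adc_fit` attribute: list(invalid_count, clamped_count, n_b_used).
#' @export
fit_adc_map <- function(series, floor_at_zero = TRUE, b_subset = NULL) {
  stopifnot(inherits(series, "dwi_series"))
  b <- series$b_values
  vols <- series$volumes
  if (!is.null(b_subset)) {
    keep <- b %in% b_subset
    if (sum(keep) < 2L) stop("`b_subset` leaves fewer than 2 b-values", call. = FALSE)
    b <- b[keep]; vols <- vols[keep]
  }
  dims <- dim(vols[[1]]$voxels)
  S <- vapply(vols, function(v) as.vector(v$voxels), numeric(prod(dims)))
  if (is.null(dim(S))) S <- matrix(S, nrow = 1L)   # single-voxel grids
  ok <- S > 0
  n_ok <- rowSums(ok)
  adc <- rep(NA_real_, nrow(S))

  full <- n_ok == length(b)
  if (any(full)) {
    bc <- b - mean(b)
    denom <- sum(bc^2)
    logS <- log(S[full, , drop = FALSE])
    adc[full] <- -as.vector(logS %*% bc) / denom
  }
  partial <- which(!full & n_ok >= 2L)
  for (v in partial) {
    use <- ok[v, ]
    bb <- b[use]
    if (length(unique(bb)) < 2L) next
    sl <- stats::cov(bb, log(S[v, use])) / stats::var(bb)
    adc[v] <- -sl
  }
  invalid <- sum(is.na(adc))
  clamped <- 0L
  if (floor_at_zero) {
    neg <- !is.na(adc) & adc < 0
    clamped <- sum(neg)
    adc[neg] <- 0
  }
  out <- image_volume(array(adc, dim = dims), vols[[1]]$spacing_mm, modality = "ADC")
  attr(out, "adc_fit") <- list(invalid_count = as.integer(invalid),
                               clamped_count = as.integer(clamped),
                               n_b_used = length(b))
  out
}

#' Fit-quality summary of an ADC map
#'
#' @param adc_map result of [fit_adc_map()].
#' @return One-row `data.frame`: invalid voxel count, clamped count, number
#'   of b-values used.
#' @export
adc_fit_summary <- function(adc_map) {
  info <- attr(adc_map, "adc_fit")
  if (is.null(info)) stop("volume carries no ADC fit record", call. = FALSE)
  data.frame(invalid_count = info$invalid_count,
             clamped_count = info$clamped_count,
             n_b_used = info$n_b_used)
}
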