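#' Image volume with anisotropic voxel spacing
#'
#' Lightweight container for a 3D intensity grid together with its voxel
#' spacing in millimetres and a modality tag. Endovaginal cervical protocols
#' reconstruct strongly anisotropic voxels (around 0.35--0.45 mm in-plane with
#' 2 mm slices), so the spacing travels with the grid everywhere: volume
#' computation, phantom generation and texture offsets all consume it.
#'
#' @param voxels numeric 3D array of intensities.
#' @param spacing_mm numeric length-3 vector: in-plane x, in-plane y, slice
#'   spacing, all in mm and strictly positive.
#' @param modality one of `"T2W"`, `"ADC"`, or a `"DWI-b<value>"` tag.
#' @return An object of class `image_volume`: a list with elements `voxels`,
#'   `spacing_mm` and `modality`.
#' @export
image_volume <- function(voxels, spacing_mm, modality = "T2W") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers (mm)", call. = FALSE)
  if (!(modality %in% c("T2W", "ADC") || grepl("^DWI-b", modality)))
    stop("`modality` must be 'T2W', 'ADC' or 'DWI-b<value>'", call. = FALSE)
  structure(list(voxels = voxels, spacing_mm = spacing_mm, modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %s voxels  spacing %s mm\n",
              x$modality, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = " x ")))
  invisible(x)
}

#' Binary volume-of-interest mask
#'
#' A VOI mask shares the exact grid and spacing of its paired volume; no
#' implicit resampling is ever performed (T2-W and ADC tumour outlines are
#' delineated on their own grids).
#'
#' @param voxels logical or 0/1 3D array.
#' @param spacing_mm voxel spacing in mm (see [image_volume()]).
#' @return An object of class `voi_mask` with logical `voxels`.
#' @export
voi_mask <- function(voxels, spacing_mm) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("mask `voxels` must be a 3D array", call. = FALSE)
  if (!is.logical(voxels)) {
    if (!all(voxels %in% c(0, 1)))
      stop("mask values must be binary (0/1 or logical)", call. = FALSE)
    voxels <- array(voxels > 0, dim = dim(voxels))
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers (mm)", call. = FALSE)
  structure(list(voxels = voxels, spacing_mm = spacing_mm), class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s grid  %d foreground voxels  (%.4g cm^3)\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels),
              voi_volume_cm3(x)))
  invisible(x)
}

check_mask_matches <- function(volume, mask) {
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop(sprintf("mask grid %s does not match volume grid %s",
                 paste(dim(mask$voxels), collapse = "x"),
                 paste(dim(volume$voxels), collapse = "x")), call. = FALSE)
  if (max(abs(volume$spacing_mm - mask$spacing_mm)) > 1e-6)
    stop("mask and volume voxel spacings differ; resample explicitly first",
         call. = FALSE)
  invisible(TRUE)
}

#' Read a volume or mask from a NIfTI file
#'
#' Spacing is taken from the NIfTI pixdim field and must be present and
#' positive; it is never silently defaulted.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param modality modality tag to attach (`"T2W"`, `"ADC"`, `"DWI-b..."`).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = "T2W") {
  if (!file.exists(path))
    stop(sprintf("volume file does not exist: '%s'", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (length(spacing) < 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop(sprintf("'%s': NIfTI pixdim missing or non-positive; refusing to default spacing",
                 path), call. = FALSE)
  # pixdim is float32 in the NIfTI header; undo the single-precision jitter
  spacing <- signif(spacing, 6)
  vox <- as.array(img)
  if (length(dim(vox)) == 2L) dim(vox) <- c(dim(vox), 1L)
  if (length(dim(vox)) > 3L) {
    if (all(dim(vox)[-seq_len(3)] == 1L)) dim(vox) <- dim(vox)[seq_len(3)]
    else stop(sprintf("'%s' is not a single 3D volume", path), call. = FALSE)
  }
  image_volume(vox, spacing, modality)
}

#' Write a volume (or mask) to a NIfTI file
#'
#' @param vol an [image_volume()] or [voi_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "voi_mask")) {
    vox <- array(as.double(vol$voxels), dim = dim(vol$voxels))
    spacing <- vol$spacing_mm
  } else if (inherits(vol, "image_volume")) {
    vox <- vol$voxels
    spacing <- vol$spacing_mm
  } else stop("`vol` must be an image_volume or voi_mask", call. = FALSE)
  img <- RNifti::asNifti(vox)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI mask
#'
#' @param path file path; voxels > 0.5 are foreground.
#' @return A [voi_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path, modality = "T2W")
  voi_mask(array(v$voxels > 0.5, dim = dim(v$voxels)), v$spacing_mm)
}

#' Aggregate per-slice 2D masks into one 3D VOI
#'
#' Tumour outlines are drawn slice by slice; the analysis operates on the
#' aggregated 3D volume of interest. Slice indices are 1-based (R array
#' convention) along the third (slice) axis.
#'
#' @param slices list of `list(index = k, mask = <2D logical/0-1 matrix>)`.
#'   May be empty, giving an all-zero VOI.
#' @param grid_shape integer length-3 grid dimensions.
#' @param spacing_mm voxel spacing in mm.
#' @return A [voi_mask()] whose slice `k` equals the provided mask for `k`
#'   and is zero elsewhere.
#' @export
stack_slice_masks <- function(slices, grid_shape, spacing_mm) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be 3 positive integers", call. = FALSE)
  out <- array(FALSE, dim = grid_shape)
  idx_seen <- integer(0)
  for (s in slices) {
    k <- as.integer(s$index)
    m <- s$mask
    if (is.na(k) || k < 1L || k > grid_shape[3])
      stop(sprintf("slice index %d outside grid (1..%d)", k, grid_shape[3]),
           call. = FALSE)
    if (k %in% idx_seen)
      stop(sprintf("duplicate slice index %d", k), call. = FALSE)
    idx_seen <- c(idx_seen, k)
    if (!all(dim(m) == grid_shape[1:2]))
      stop(sprintf("slice %d mask shape %s does not match in-plane grid %s",
                   k, paste(dim(m), collapse = "x"),
                   paste(grid_shape[1:2], collapse = "x")), call. = FALSE)
    out[, , k] <- m > 0
  }
  voi_mask(out, spacing_mm)
}

#' VOI volume in cubic centimetres
#'
#' `voxel count * voxel volume (mm^3) / 1000`. Empty masks give 0.
#'
#' @param mask a [voi_mask()], or a logical/binary 3D array if `spacing_mm`
#'   is supplied.
#' @param spacing_mm spacing override (mm); defaults to the mask's own.
#' @return Volume in cm^3.
#' @export
voi_volume_cm3 <- function(mask, spacing_mm = NULL) {
  if (inherits(mask, "voi_mask")) {
    vox <- mask$voxels
    if (is.null(spacing_mm)) spacing_mm <- mask$spacing_mm
  } else vox <- mask
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers", call. = FALSE)
  sum(vox > 0) * prod(spacing_mm) / 1000
}

#' Volume of a sphere of given diameter, in cm^3
#'
#' The trachelectomy eligibility threshold used throughout the analysis is the
#' volume of a 2 cm diameter sphere: (4/3) * pi * 1^3 = 4.19 cm^3 (2 dp).
#'
#' @param diameter_cm sphere diameter in cm (default 2).
#' @return Volume in cm^3.
#' @export
sphere_volume_cm3 <- function(diameter_cm = 2) {
  stopifnot(diameter_cm > 0)
  (4 / 3) * pi * (diameter_cm / 2)^3
}

#' Rasterize an axis-aligned ellipsoid mask on an anisotropic grid
#'
#' A voxel is foreground when its centre lies inside the ellipsoid. Used by
#' the phantom generator and for sphere-threshold checks.
#'
#' @param semi_axes_mm numeric length-3 semi-axes in mm.
#' @param spacing_mm voxel spacing in mm.
#' @param margin_voxels background border added on every side.
#' @return A [voi_mask()] centred in its grid.
#' @export
rasterize_ellipsoid <- function(semi_axes_mm, spacing_mm, margin_voxels = 2L) {
  semi_axes_mm <- as.numeric(semi_axes_mm)
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(semi_axes_mm) == 3L, all(semi_axes_mm > 0),
            length(spacing_mm) == 3L, all(spacing_mm > 0))
  half_n <- ceiling(semi_axes_mm / spacing_mm) + margin_voxels
  dims <- 2L * as.integer(half_n) + 1L
  centre <- (dims + 1) / 2
  ax <- ((seq_len(dims[1]) - centre[1]) * spacing_mm[1] / semi_axes_mm[1])^2
  ay <- ((seq_len(dims[2]) - centre[2]) * spacing_mm[2] / semi_axes_mm[2])^2
  az <- ((seq_len(dims[3]) - centre[3]) * spacing_mm[3] / semi_axes_mm[3])^2
  r2 <- outer(outer(ax, ay, `+`), az, `+`)
  voi_mask(array(r2 <= 1, dim = dims), spacing_mm)
}
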