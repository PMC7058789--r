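#' Image volume and ROI mask containers
#'
#' An `image_volume` holds a 3D intensity grid (Hounsfield units for CT)
#' together with its voxel spacing in mm; a `roi_mask` holds a binary grid
#' on the same lattice. Masks must be non-empty and share the grid of their
#' companion volume.
#'
#' @param data 3D numeric (volume) or logical/0-1 (mask) array.
#' @param spacing length-3 positive numeric, voxel spacing in mm (x, y, z).
#' @return An object of class `image_volume` or `roi_mask`.
#' @examples
#' v <- image_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), c(1, 1, 5))
#' m <- roi_mask(array(TRUE, c(8, 8, 4)), c(1, 1, 5))
#' @export
image_volume <- function(data, spacing) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume must be a 3D array", call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume intensities must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' @rdname image_volume
#' @export
roi_mask <- function(data, spacing) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  data <- array(data != 0, dim(data))
  if (!any(data))
    stop("empty ROI: mask has no foreground voxel", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Read a volume/mask pair from NIfTI files
#'
#' Spacing is taken from the NIfTI header. The mask must live on the same
#' grid as the volume (same array shape and spacing); a mismatch raises an
#' incompatible-grid error rather than silently resampling.
#'
#' @param volume_path,mask_path paths to NIfTI-1 files (`.nii` / `.nii.gz`).
#' @return A list with elements `volume` ([image_volume]) and `mask`
#'   ([roi_mask]).
#' @export
read_case <- function(volume_path, mask_path) {
  vimg <- RNifti::readNifti(volume_path)
  mimg <- RNifti::readNifti(mask_path)
  vsp <- RNifti::pixdim(vimg)[1:3]
  msp <- RNifti::pixdim(mimg)[1:3]
  varr <- array(as.numeric(vimg), dim(vimg)[1:3])
  marr <- array(as.numeric(mimg), dim(mimg)[1:3])
  if (!identical(dim(varr), dim(marr)) ||
      max(abs(vsp - msp)) > 1e-4)
    stop("incompatible grid: mask shape/spacing differs from volume",
         call. = FALSE)
  if (!any(marr != 0))
    stop("empty ROI: mask has no foreground voxel", call. = FALSE)
  list(volume = image_volume(varr, vsp), mask = roi_mask(marr, msp))
}

#' Write a volume/mask pair as NIfTI files
#'
#' @param volume an [image_volume].
#' @param mask a [roi_mask] on the same grid.
#' @param volume_path,mask_path output paths (`.nii` / `.nii.gz`).
#' @return Invisibly, the two paths.
#' @export
write_case <- function(volume, mask, volume_path, mask_path) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  vimg <- RNifti::asNifti(volume$data)
  RNifti::pixdim(vimg) <- volume$spacing
  RNifti::writeNifti(vimg, volume_path)
  mimg <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::pixdim(mimg) <- mask$spacing
  RNifti::writeNifti(mimg, mask_path)
  invisible(c(volume_path, mask_path))
}

# Trilinear sample of a 3D array at (fractional) 0-based voxel coordinates.
trilinear_sample <- function(arr, cx, cy, cz) {
  d <- dim(arr)
  clamp <- function(v, hi) pmin(pmax(v, 0), hi)
  cx <- clamp(cx, d[1] - 1); cy <- clamp(cy, d[2] - 1); cz <- clamp(cz, d[3] - 1)
  x0 <- floor(cx); y0 <- floor(cy); z0 <- floor(cz)
  x1 <- pmin(x0 + 1, d[1] - 1)
  y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  at <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  v000 <- at(x0, y0, z0); v100 <- at(x1, y0, z0)
  v010 <- at(x0, y1, z0); v110 <- at(x1, y1, z0)
  v001 <- at(x0, y0, z1); v101 <- at(x1, y0, z1)
  v011 <- at(x0, y1, z1); v111 <- at(x1, y1, z1)
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}

#' Resample a volume and mask to a normalized voxel size
#'
#' Intensities are interpolated trilinearly, the mask with nearest
#' neighbour so it stays binary. The default target spacing of 1 x 1 x 5 mm
#' normalizes heterogeneous acquisitions before feature extraction. Voxel
#' `i` (1-based) is placed at world coordinate `(i - 1) * spacing`, so a
#' resample onto the input spacing is the identity.
#'
#' @param volume an [image_volume].
#' @param mask a [roi_mask] on the same grid.
#' @param target_spacing length-3 positive numeric, mm.
#' @return A list with resampled `volume` and `mask`.
#' @export
resample <- function(volume, mask, target_spacing = c(1, 1, 5)) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0) ||
      any(!is.finite(target_spacing)))
    stop("target spacing must be three positive numbers", call. = FALSE)
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("incompatible grid: mask shape differs from volume", call. = FALSE)
  sp <- volume$spacing
  d <- dim(volume$data)
  if (max(abs(sp - target_spacing)) < 1e-9)
    return(list(volume = volume, mask = mask))
  nd <- pmax(1L, as.integer(round(d * sp / target_spacing)))
  # 0-based target voxel coords in source voxel units
  gx <- (seq_len(nd[1]) - 1) * target_spacing[1] / sp[1]
  gy <- (seq_len(nd[2]) - 1) * target_spacing[2] / sp[2]
  gz <- (seq_len(nd[3]) - 1) * target_spacing[3] / sp[3]
  cx <- rep(gx, times = nd[2] * nd[3])
  cy <- rep(rep(gy, each = nd[1]), times = nd[3])
  cz <- rep(gz, each = nd[1] * nd[2])
  vout <- array(trilinear_sample(volume$data, cx, cy, cz), nd)
  d1 <- dim(mask$data)
  nn <- function(v, hi) pmin(pmax(round(v), 0), hi)
  mout <- array(mask$data[cbind(nn(cx, d1[1] - 1) + 1,
                                nn(cy, d1[2] - 1) + 1,
                                nn(cz, d1[3] - 1) + 1)], nd)
  if (!any(mout))
    stop("empty ROI: resampling removed all foreground voxels", call. = FALSE)
  list(volume = image_volume(vout, target_spacing),
       mask = roi_mask(mout, target_spacing))
}

#' Quantize ROI intensities to a fixed number of gray levels
#'
#' Equal-width binning over the ROI intensity range:
#' `level(v) = min(n_levels, 1 + floor(n_levels * (v - min) / (max - min)))`.
#' A constant ROI maps every voxel to level 1. Quantization depends only on
#' the ROI's intensity ranks within its own range, so it is invariant to
#' affine rescaling `v -> a * v + b` (a > 0) of the input.
#'
#' @param volume an [image_volume].
#' @param mask a [roi_mask] on the same grid.
#' @param n_levels number of gray levels (default 64).
#' @return An object of class `quantized_roi` with fields `levels` (integer
#'   array, 0 outside the ROI), `n_levels`, `dims`, and `bin_range` (the
#'   intensity min/max defining the map).
#' @export
quantize_roi <- function(volume, mask, n_levels = 64L) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be >= 2", call. = FALSE)
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("incompatible grid: mask shape differs from volume", call. = FALSE)
  v <- volume$data[mask$data]
  lo <- min(v); hi <- max(v)
  lev <- array(0L, dim(volume$data))
  if (hi - lo <= 0) {
    lev[mask$data] <- 1L
  } else {
    lev[mask$data] <- pmin(n_levels,
                           1L + as.integer(floor(n_levels * (v - lo) / (hi - lo))))
  }
  structure(list(levels = lev, n_levels = n_levels, dims = dim(lev),
                 bin_range = c(lo, hi)),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %d ROI voxels, %d levels (observed %d distinct)\n",
              sum(x$levels > 0), x$n_levels,
              length(unique(x$levels[x$levels > 0]))))
  invisible(x)
}
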