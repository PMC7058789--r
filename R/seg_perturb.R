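#' Segmentation-perturbation specification
#'
#' Controls the random per-slice expansion/erosion that mimics manual
#' segmentation uncertainty: each axial slice of the mask independently
#' draws an action among expand / erode / keep (uniform thirds) and, for
#' expand/erode, an in-plane disk radius drawn uniformly from
#' `min_px..max_px` pixels.
#'
#' @param min_px,max_px radius range in pixels (`1 <= min_px <= max_px`).
#' @param n_variants number of perturbed variants generated alongside the
#'   original (default 2, giving three segmentation sets).
#' @param seed integer seed for the counter-based action stream.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(min_px = 1L, max_px = 4L, n_variants = 2L,
                              seed = 1L) {
  min_px <- as.integer(min_px); max_px <- as.integer(max_px)
  n_variants <- as.integer(n_variants)
  if (min_px < 1L || max_px < min_px)
    stop("need 1 <= min_px <= max_px", call. = FALSE)
  if (n_variants < 0L) stop("n_variants must be >= 0", call. = FALSE)
  structure(list(min_px = min_px, max_px = max_px,
                 n_variants = n_variants, seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Disk structuring element
#'
#' Binary in-plane kernel containing every pixel offset `(dx, dy)` with
#' `dx^2 + dy^2 <= r^2`.
#'
#' @param r radius in pixels (>= 1).
#' @return `(2r+1) x (2r+1)` 0/1 matrix.
#' @export
disk_kernel <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 1L)
  off <- -r:r
  k <- outer(off^2, off^2, "+") <= r^2
  matrix(as.numeric(k), nrow = 2L * r + 1L)
}

# Morphology on one binary slice via EBImage with our disk kernel.
slice_morph <- function(slice, action, r) {
  if (action == "keep") return(slice)
  k <- disk_kernel(r)
  img <- matrix(as.numeric(slice), nrow = nrow(slice))
  out <- if (action == "expand") EBImage::dilate(img, k) else
    EBImage::erode(img, k)
  matrix(out > 0.5, nrow = nrow(slice))
}

# Draw (action, radius) for one slice from the counter stream.
slice_draw <- function(spec, variant_index, slice_index) {
  u <- counter_runif(2L, spec$seed, 7000L + variant_index, slice_index)
  action <- c("keep", "expand", "erode")[1L + floor(u[1] * 3) %% 3]
  radius <- spec$min_px +
    floor(u[2] * (spec$max_px - spec$min_px + 1L)) %%
      (spec$max_px - spec$min_px + 1L)
  list(action = action, radius = as.integer(radius))
}

#' Randomly expand/erode a mask slice-by-slice
#'
#' Each axial (z) slice containing foreground draws an action in
#' \{expand, erode, keep\} and a disk radius in `min_px..max_px`, then 2D
#' morphological dilation or erosion is applied in-plane. A slice fully
#' erased by erosion is restored to its centroid voxel so the result stays
#' non-empty. The draw stream is counter-based and keyed by
#' `(seed, variant_index, slice_index)`, so results are independent of
#' evaluation order and reproducible.
#'
#' @param mask a [roi_mask].
#' @param spec a [perturbation_spec].
#' @param variant_index which variant to generate (1-based integer).
#' @param action_override optional fixed action (`"keep"`, `"expand"`,
#'   `"erode"`) applied to every slice, bypassing the random stream;
#'   intended for diagnostics.
#' @return A perturbed [roi_mask].
#' @export
perturb_mask <- function(mask, spec, variant_index = 1L,
                         action_override = NULL) {
  stopifnot(inherits(mask, "roi_mask"), inherits(spec, "perturbation_spec"))
  m <- mask$data
  nz <- dim(m)[3]
  out <- m
  for (z in seq_len(nz)) {
    sl <- m[, , z]
    if (!any(sl)) next
    if (is.null(action_override)) {
      dr <- slice_draw(spec, variant_index, z)
    } else {
      dr <- list(action = match.arg(action_override,
                                    c("keep", "expand", "erode")),
                 radius = spec$max_px)
    }
    new_sl <- slice_morph(sl, dr$action, dr$radius)
    if (!any(new_sl)) {
      # erosion erased the slice: keep a single voxel at the centroid
      idx <- which(sl, arr.ind = TRUE)
      cen <- round(colMeans(idx))
      # snap to the nearest foreground pixel of the original slice
      d2 <- (idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2
      keep <- idx[which.min(d2), , drop = FALSE]
      new_sl <- matrix(FALSE, nrow(sl), ncol(sl))
      new_sl[keep] <- TRUE
    }
    out[, , z] <- new_sl
  }
  roi_mask(out, mask$spacing)
}

#' Build the set of segmentations used for robustness screening
#'
#' @param mask a [roi_mask].
#' @param spec a [perturbation_spec].
#' @return List of [roi_mask]s: the untouched mask first, followed by
#'   `n_variants` perturbed variants.
#' @export
make_segmentation_set <- function(mask, spec = perturbation_spec()) {
  stopifnot(inherits(mask, "roi_mask"), inherits(spec, "perturbation_spec"))
  out <- vector("list", spec$n_variants + 1L)
  out[[1]] <- mask
  for (v in seq_len(spec$n_variants))
    out[[v + 1L]] <- perturb_mask(mask, spec, v)
  out
}

#' Dice overlap between two masks
#'
#' @param a,b [roi_mask]s on the same grid.
#' @return Dice coefficient `2|A n B| / (|A| + |B|)`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"),
            identical(dim(a$data), dim(b$data)))
  2 * sum(a$data & b$data) / (sum(a$data) + sum(b$data))
}
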