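# Daubechies 4-vanishing-moment (8-tap) orthonormal low-pass filter.
DB4_LO <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
            -0.027983769416984, -0.187034811718881, 0.030841381835987,
            0.032883011666983, -0.010597401784997)

wavelet_filters <- function(name = "db4") {
  name <- match.arg(name, "db4")
  h <- DB4_LO
  n <- length(h)
  g <- rev(h) * (-1)^(seq_len(n) - 1)  # quadrature mirror filter
  # 1/sqrt(2) scaling makes the undecimated analysis a tight frame with
  # bound 1: the 8 subband energies sum exactly to the input energy.
  list(lo = h / sqrt(2), hi = g / sqrt(2))
}

#' Single-level undecimated 3D wavelet decomposition
#'
#' Separable stationary (undecimated) wavelet transform: the volume is
#' circularly convolved with the low-pass (L) or high-pass (H) filter along
#' each axis in turn, producing 8 subbands labelled by the per-axis filter
#' sequence in x, y, z order (`LLL` ... `HHH`). Because no decimation is
#' performed, every subband has the shape of the input and the original ROI
#' mask applies unchanged. Filters are scaled so the decomposition is a
#' tight frame: subband energies sum to the input energy.
#'
#' @param volume an [image_volume].
#' @param wavelet filter family (currently the orthogonal 8-tap `"db4"`).
#' @return Named list of 8 [image_volume]s (`LLL`, `LLH`, ..., `HHH`),
#'   with attribute `wavelet`.
#' @export
wavelet_decompose <- function(volume, wavelet = "db4") {
  stopifnot(inherits(volume, "image_volume"))
  f <- wavelet_filters(wavelet)
  d <- dim(volume$data)
  if (any(d < length(f$lo)))
    stop("invalid argument: volume smaller than the wavelet filter support",
         call. = FALSE)
  centre <- length(f$lo) %/% 2L  # approximate group-delay alignment
  pass <- function(arr, which, axis)
    apply_axis_filter(arr, if (which == "L") f$lo else f$hi, axis,
                      center = centre)
  lx <- pass(volume$data, "L", 1); hx <- pass(volume$data, "H", 1)
  out <- list()
  for (fy in c("L", "H")) {
    xy_l <- pass(lx, fy, 2); xy_h <- pass(hx, fy, 2)
    for (fz in c("L", "H")) {
      out[[paste0("L", fy, fz)]] <- image_volume(pass(xy_l, fz, 3),
                                                 volume$spacing)
      out[[paste0("H", fy, fz)]] <- image_volume(pass(xy_h, fz, 3),
                                                 volume$spacing)
    }
  }
  out <- out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
  attr(out, "wavelet") <- wavelet
  out
}
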