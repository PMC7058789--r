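#' Feature extraction configuration
#'
#' Freezes every constant of the quantification stage so that feature
#' tables from different runs are joinable: target voxel spacing, number of
#' gray levels, co-occurrence distance, wavelet family, and the feature
#' families computed. The default configuration yields 47 features per
#' image (7 histogram + 9 GLCM + 13 GLRLM + 13 GLSZM + 5 NGTDM) on the
#' original image and each of the 8 wavelet subbands: 423 named features.
#'
#' @param n_levels gray levels for ROI quantization (default 64).
#' @param distance co-occurrence offset distance in voxels (default 1).
#' @param spacing target voxel spacing in mm (default `c(1, 1, 5)`).
#' @param wavelet wavelet family for subband features, or `NULL` to skip
#'   subbands.
#' @param families character vector of feature families to compute.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(n_levels = 64L, distance = 1L,
                           spacing = c(1, 1, 5), wavelet = "db4",
                           families = c("Histogram", "GLCM", "GLRLM",
                                        "GLSZM", "NGTDM")) {
  families <- match.arg(families, several.ok = TRUE)
  structure(list(n_levels = as.integer(n_levels),
                 distance = as.integer(distance),
                 spacing = as.numeric(spacing),
                 wavelet = wavelet,
                 families = families),
            class = "feature_config")
}

FAMILY_FEATURES <- list(
  Histogram = c("Mean", "Variance", "Skewness", "Kurtosis", "Energy",
                "Entropy", "Uniformity"),
  GLCM = c("Energy", "Contrast", "Entropy", "Homogeneity", "Correlation",
           "SumAverage", "Variance", "Dissimilarity", "Autocorrelation"),
  GLRLM = c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE", "SRLGE",
            "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV"),
  GLSZM = c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE", "SZLGE",
            "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV"),
  NGTDM = c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
)

SUBBAND_LABELS <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

#' Registry of feature names implied by a configuration
#'
#' Names follow `<Subband_>Family_Feature`; features of the original
#' (unfiltered) image carry no subband prefix.
#'
#' @param config a [feature_config].
#' @return Character vector of feature names, in extraction order.
#' @export
feature_names <- function(config = feature_config()) {
  per_image <- unlist(lapply(config$families, function(f)
    paste(f, FAMILY_FEATURES[[f]], sep = "_")), use.names = FALSE)
  prefixes <- if (is.null(config$wavelet)) "" else
    c("", paste0(SUBBAND_LABELS, "_"))
  unlist(lapply(prefixes, function(p) paste0(p, per_image)),
         use.names = FALSE)
}

#' Histogram features of a quantized ROI
#'
#' First-order statistics of the gray-level distribution `p(i)` over the
#' ROI: mean, variance, skewness, kurtosis, energy (second raw moment of
#' the levels), entropy (bits), and uniformity. Zero-variance ROIs take
#' skewness = kurtosis = 0 by convention so degenerate inputs stay finite.
#'
#' @param q a `quantized_roi` (see [quantize_roi()]).
#' @return Named numeric vector of 7 features.
#' @export
histogram_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  lev <- q$levels[q$levels > 0L]
  i <- seq_len(q$n_levels)
  p <- tabulate(lev, nbins = q$n_levels) / length(lev)
  mu <- sum(i * p)
  v <- sum((i - mu)^2 * p)
  if (v > 0) {
    skew <- sum((i - mu)^3 * p) / v^1.5
    kurt <- sum((i - mu)^4 * p) / v^2
  } else {
    skew <- 0
    kurt <- 0
  }
  c(Mean = mu,
    Variance = v,
    Skewness = skew,
    Kurtosis = kurt,
    Energy = sum(i^2 * p),
    Entropy = -sum(p[p > 0] * log2(p[p > 0])),
    Uniformity = sum(p^2))
}

#' Gray-level co-occurrence matrix and features
#'
#' Co-occurrences are counted over the requested subset of the 13 unique 3D
#' direction offsets at the given distance, both orderings of each voxel
#' pair (symmetric matrix), restricted to pairs with both voxels inside the
#' ROI, summed over directions. `glcm_features()` normalizes the counts to
#' probabilities and computes energy, contrast, entropy, homogeneity,
#' correlation, sum average, variance, dissimilarity and autocorrelation.
#'
#' @param q a `quantized_roi`.
#' @param distance offset length in voxels.
#' @param directions integer subset of `1:13`.
#' @param m a co-occurrence count matrix from `glcm_matrix()`.
#' @return `glcm_matrix()`: an `n_levels x n_levels` count matrix;
#'   `glcm_features()`: named numeric vector of 9 features.
#' @export
glcm_matrix <- function(q, distance = 1L, directions = 1:13) {
  stopifnot(inherits(q, "quantized_roi"))
  m <- .glcm_counts(as.integer(q$levels), as.integer(q$dims),
                    q$n_levels, as.integer(distance), as.integer(directions))
  if (sum(m) == 0)
    stop("no pairs: ROI has no co-occurring voxel pair at this distance",
         call. = FALSE)
  m
}

#' @rdname glcm_matrix
#' @export
glcm_features <- function(m) {
  p <- m / sum(m)
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  pi_m <- rowSums(p)  # symmetric: row and column marginals agree
  mu <- sum(seq_len(ng) * pi_m)
  sig2 <- sum((seq_len(ng) - mu)^2 * pi_m)
  corr <- if (sig2 > 1e-12)
    sum((i - mu) * (j - mu) * p) / sig2 else 1
  c(Energy = sum(p^2),
    Contrast = sum((i - j)^2 * p),
    Entropy = -sum(p[p > 0] * log2(p[p > 0])),
    Homogeneity = sum(p / (1 + abs(i - j))),
    Correlation = corr,
    SumAverage = sum((i + j) * p),
    Variance = sig2,
    Dissimilarity = sum(abs(i - j) * p),
    Autocorrelation = sum(i * j * p))
}

# shared level/size-style feature block for GLRLM and GLSZM
rl_sz_features <- function(m, n_vox, names2) {
  nr <- sum(m)
  p <- m / nr
  i <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  j <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  out <- c(sum(p / j^2),                      # short emphasis
           sum(p * j^2),                      # long emphasis
           sum(rowSums(m)^2) / nr,            # gray-level non-uniformity
           sum(colSums(m)^2) / nr,            # size non-uniformity
           nr / n_vox,                        # percentage
           sum(p / i^2),                      # low gray-level
           sum(p * i^2),                      # high gray-level
           sum(p / (i^2 * j^2)),
           sum(p * i^2 / j^2),
           sum(p * j^2 / i^2),
           sum(p * i^2 * j^2),
           sum(p * (i - mu_i)^2),             # gray-level variance
           sum(p * (j - mu_j)^2))             # length/size variance
  names(out) <- names2
  out
}

#' Gray-level run-length matrix and features
#'
#' Runs of equal consecutive gray level are counted along the 13 unique 3D
#' directions (runs are truncated wherever the line leaves the ROI) and the
#' per-direction matrices are merged by summation. Features are the 13
#' standard run-length statistics (SRE, LRE, GLN, RLN, RP, LGRE, HGRE,
#' SRLGE, SRHGE, LRLGE, LRHGE, GLV, RLV).
#'
#' @param q a `quantized_roi`.
#' @param directions integer subset of `1:13`.
#' @param m a run-length count matrix from `glrlm_matrix()`.
#' @param n_vox ROI voxel count entering the run percentage; taken from the
#'   matrix attribute when omitted.
#' @return `glrlm_matrix()`: count matrix (levels x run length, trailing
#'   all-zero columns trimmed, attribute `n_vox`); `glrlm_features()`:
#'   named numeric vector of 13 features.
#' @export
glrlm_matrix <- function(q, directions = 1:13) {
  stopifnot(inherits(q, "quantized_roi"))
  m <- .glrlm_counts(as.integer(q$levels), as.integer(q$dims),
                     q$n_levels, as.integer(directions))
  keep <- max(which(colSums(m) > 0))
  m <- m[, seq_len(keep), drop = FALSE]
  attr(m, "n_vox") <- sum(q$levels > 0L) * length(directions)
  m
}

#' @rdname glrlm_matrix
#' @export
glrlm_features <- function(m, n_vox = attr(m, "n_vox")) {
  rl_sz_features(m, n_vox,
                 c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                   "SRLGE", "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV"))
}

#' Gray-level size-zone matrix and features
#'
#' Zones are 26-connected components of equal-level voxels within the ROI;
#' the matrix counts zones by (level, size). Features are the 13 standard
#' size-zone statistics; `GLSZM_GLV` is the probability-weighted variance
#' of the zone gray levels.
#'
#' @param q a `quantized_roi`.
#' @param m a size-zone count matrix from `glszm_matrix()`.
#' @param n_vox ROI voxel count; taken from the matrix attribute when
#'   omitted.
#' @return `glszm_matrix()`: count matrix (levels x zone size, attribute
#'   `n_vox`); `glszm_features()`: named numeric vector of 13 features.
#' @export
glszm_matrix <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  z <- .glszm_zones(as.integer(q$levels), as.integer(q$dims))
  msz <- max(z[, 2])
  m <- matrix(0, q$n_levels, msz)
  for (r in seq_len(nrow(z)))
    m[z[r, 1], z[r, 2]] <- m[z[r, 1], z[r, 2]] + 1
  attr(m, "n_vox") <- sum(q$levels > 0L)
  m
}

#' @rdname glszm_matrix
#' @export
glszm_features <- function(m, n_vox = attr(m, "n_vox")) {
  rl_sz_features(m, n_vox,
                 c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE",
                   "SZLGE", "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV"))
}

#' Neighbourhood gray-tone difference matrix and features
#'
#' For each gray level `i`, `s(i)` sums, over ROI voxels at level `i`, the
#' absolute difference between `i` and the mean level of the voxel's
#' 26-neighbourhood restricted to the ROI (voxels with no ROI neighbour
#' contribute 0). Features are the Amadasun-King coarseness, contrast,
#' busyness, complexity and strength; the coarseness denominator is floored
#' at `1e-12` so a flat ROI yields a large finite value instead of
#' infinity.
#'
#' @param q a `quantized_roi`.
#' @param m an NGTDM matrix from `ngtdm_matrix()`.
#' @return `ngtdm_matrix()`: matrix with columns `s` and `n` (one row per
#'   gray level); `ngtdm_features()`: named numeric vector of 5 features.
#' @export
ngtdm_matrix <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  m <- .ngtdm_stats(as.integer(q$levels), as.integer(q$dims), q$n_levels)
  colnames(m) <- c("s", "n")
  m
}

#' @rdname ngtdm_matrix
#' @export
ngtdm_features <- function(m) {
  eps <- 1e-12
  s <- m[, "s"]
  n <- m[, "n"]
  N <- sum(n)
  p <- n / N
  present <- which(p > 0)
  ngp <- length(present)
  i <- present
  coarseness <- 1 / max(sum(p * s), eps)
  if (ngp > 1) {
    pi_ <- p[present]
    si_ <- s[present]
    dmat <- outer(i, i, "-")
    contrast <- sum(outer(pi_, pi_) * dmat^2) / (ngp * (ngp - 1)) * sum(s) / N
    denom_b <- sum(abs(outer(i * pi_, i * pi_, "-")))
    busyness <- if (denom_b > eps) sum(p * s) / denom_b else 0
    psum <- outer(pi_, pi_, "+")
    pscaled <- outer(pi_ * si_, pi_ * si_, function(a, b) a + b)
    complexity <- sum(abs(dmat) * pscaled / psum) / N
    strength <- sum(psum * dmat^2) / max(sum(s), eps)
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

# All configured families for one already-quantized image.
image_features <- function(q, config) {
  out <- numeric(0)
  for (fam in config$families) {
    f <- switch(fam,
      Histogram = histogram_features(q),
      GLCM = glcm_features(glcm_matrix(q, distance = config$distance)),
      GLRLM = glrlm_features(glrlm_matrix(q)),
      GLSZM = glszm_features(glszm_matrix(q)),
      NGTDM = ngtdm_features(ngtdm_matrix(q)))
    names(f) <- paste(fam, names(f), sep = "_")
    out <- c(out, f)
  }
  out
}

#' Extract the full radiomics feature vector of one case
#'
#' Pipeline: resample volume and mask to the configured spacing, decompose
#' the volume into 8 undecimated wavelet subbands (which share the original
#' grid, so the mask applies unchanged), quantize the original image and
#' each subband to `n_levels` gray levels within the ROI, and compute every
#' configured feature family on each image. With the default configuration
#' this yields 423 named features per case.
#'
#' @param volume an [image_volume].
#' @param mask a [roi_mask] on the same grid.
#' @param config a [feature_config].
#' @return Named numeric vector, names as in [feature_names()].
#' @export
extract_all <- function(volume, mask, config = feature_config()) {
  rs <- resample(volume, mask, config$spacing)
  images <- list(rs$volume)
  prefixes <- ""
  if (!is.null(config$wavelet)) {
    wb <- wavelet_decompose(rs$volume, config$wavelet)
    images <- c(images, wb)
    prefixes <- c("", paste0(SUBBAND_LABELS, "_"))
  }
  out <- numeric(0)
  for (k in seq_along(images)) {
    q <- quantize_roi(images[[k]], rs$mask, config$n_levels)
    f <- image_features(q, config)
    names(f) <- paste0(prefixes[k], names(f))
    out <- c(out, f)
  }
  if (!all(is.finite(out)))
    stop("non-finite feature value produced", call. = FALSE)
  out
}

#' Extract a feature table for a cohort
#'
#' @param cohort a `synthetic_cohort` (or any list of cases with `volume`,
#'   `mask`, `patient_id` entries).
#' @param config a [feature_config].
#' @param masks optional list of [roi_mask]s overriding each case's own
#'   mask (used for perturbed-segmentation feature tables).
#' @return `data.frame` with `patient_id` and one column per feature.
#' @export
extract_table <- function(cohort, config = feature_config(), masks = NULL) {
  cases <- if (inherits(cohort, "synthetic_cohort")) cohort$cases else cohort
  rows <- lapply(seq_along(cases), function(k) {
    cs <- cases[[k]]
    m <- if (is.null(masks)) cs$mask else masks[[k]]
    extract_all(cs$volume, m, config)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  data.frame(patient_id = vapply(cases, `[[`, character(1), "patient_id"),
             tab, check.names = FALSE, stringsAsFactors = FALSE)
}
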