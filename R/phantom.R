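#' Class specification for the synthetic phantom generator
#'
#' A `class_spec` fixes the statistical signature of one tumour subtype in
#' the synthetic cohort: the spatial correlation length of the intensity
#' texture, the target skewness of the ROI intensity histogram, the number
#' of active intensity levels (which controls histogram entropy and
#' uniformity), the HU scale, and class-conditional clinical covariates
#' (log-normal CA 19-9 and CEA, normal age, Bernoulli sex).
#'
#' @param label subtype label, one of `"SCA"`, `"MCN"`, `"IPMN"`.
#' @param texture_corr_length spatial correlation length of the intensity
#'   field, mm (> 0).
#' @param hist_skew target skewness of ROI intensities.
#' @param hist_levels_active number of distinct intensity levels the ROI
#'   spans (>= 1; 1 gives a constant ROI).
#' @param mean_hu,sd_hu ROI intensity location and scale in HU (`sd_hu` > 0).
#' @param ca199_log_mean,ca199_log_sd log-scale parameters of serum CA 19-9
#'   (U/mL).
#' @param cea_log_mean,cea_log_sd log-scale parameters of serum CEA (ng/mL).
#' @param age_mean,age_sd age distribution in years (truncated to 18-90 at
#'   draw time).
#' @param female_prob probability of female sex, in `[0, 1]`.
#' @return An object of class `class_spec`.
#' @examples
#' class_spec("SCA", texture_corr_length = 3, hist_skew = -0.6,
#'            hist_levels_active = 36)
#' @export
class_spec <- function(label,
                       texture_corr_length = 4,
                       hist_skew = 0,
                       hist_levels_active = 24,
                       mean_hu = 40, sd_hu = 12,
                       ca199_log_mean = log(10), ca199_log_sd = 1,
                       cea_log_mean = log(2), cea_log_sd = 0.6,
                       age_mean = 55, age_sd = 12,
                       female_prob = 0.7) {
  label <- match.arg(label, c("SCA", "MCN", "IPMN"))
  if (!is.finite(texture_corr_length) || texture_corr_length <= 0)
    stop("texture_corr_length must be > 0", call. = FALSE)
  if (!is.finite(female_prob) || female_prob < 0 || female_prob > 1)
    stop("female_prob must be in [0, 1]", call. = FALSE)
  for (s in c(sd_hu, ca199_log_sd, cea_log_sd, age_sd))
    if (!is.finite(s) || s < 0) stop("sd parameters must be >= 0", call. = FALSE)
  if (sd_hu <= 0) stop("sd_hu must be > 0", call. = FALSE)
  hist_levels_active <- as.integer(hist_levels_active)
  if (hist_levels_active < 1L)
    stop("hist_levels_active must be >= 1", call. = FALSE)
  structure(list(label = label,
                 texture_corr_length = texture_corr_length,
                 hist_skew = hist_skew,
                 hist_levels_active = hist_levels_active,
                 mean_hu = mean_hu, sd_hu = sd_hu,
                 ca199_log_mean = ca199_log_mean, ca199_log_sd = ca199_log_sd,
                 cea_log_mean = cea_log_mean, cea_log_sd = cea_log_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 female_prob = female_prob),
            class = "class_spec")
}

#' Default subtype specifications
#'
#' Three well-separated `class_spec`s encoding the qualitative clinical
#' picture of the subtypes: serous cystadenoma (SCA) with many active
#' intensity levels and left-skewed histogram, predominantly female, low
#' tumour markers; mucinous cystic neoplasm (MCN) with few levels, almost
#' exclusively female, moderately elevated markers; intraductal papillary
#' mucinous neoplasm (IPMN) with strongly right-skewed histogram, older and
#' more often male patients, highest CA 19-9 and CEA. The pooled marker
#' scale is anchored to cohort medians (CA 19-9 ~ 10 U/mL, CEA ~ 2 ng/mL).
#'
#' @return Named list of three [class_spec]s (`SCA`, `MCN`, `IPMN`).
#' @export
default_class_specs <- function() {
  list(
    SCA = class_spec("SCA", texture_corr_length = 3, hist_skew = -0.6,
                     hist_levels_active = 36, mean_hu = 45, sd_hu = 12,
                     ca199_log_mean = log(8), ca199_log_sd = 0.9,
                     cea_log_mean = log(1.5), cea_log_sd = 0.5,
                     age_mean = 52, age_sd = 12, female_prob = 0.75),
    MCN = class_spec("MCN", texture_corr_length = 6, hist_skew = 0.4,
                     hist_levels_active = 14, mean_hu = 35, sd_hu = 10,
                     ca199_log_mean = log(25), ca199_log_sd = 1.1,
                     cea_log_mean = log(2.5), cea_log_sd = 0.7,
                     age_mean = 48, age_sd = 12, female_prob = 0.95),
    IPMN = class_spec("IPMN", texture_corr_length = 4.5, hist_skew = 1.2,
                      hist_levels_active = 24, mean_hu = 40, sd_hu = 15,
                      ca199_log_mean = log(70), ca199_log_sd = 1.3,
                      cea_log_mean = log(4), cea_log_sd = 0.8,
                      age_mean = 66, age_sd = 9, female_prob = 0.35)
  )
}

# Separable circular Gaussian smoothing along one axis (sigma in voxels).
smooth_axis <- function(arr, sigma, axis) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  apply_axis_filter(arr, k, axis, center = r + 1L)
}

# Circular convolution of `arr` with kernel `k` along `axis`; `center` is
# the 1-based index of the kernel tap aligned with the output voxel.
apply_axis_filter <- function(arr, k, axis, center) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  n <- nrow(m)
  if (length(k) > n) {
    # fold the kernel circularly onto the axis length (exact for circular
    # convolution); needed when a wide smoothing kernel meets a short axis
    off <- seq_along(k) - center
    kf <- numeric(n)
    for (j in seq_along(k)) {
      idx <- (off[j] %% n) + 1L
      kf[idx] <- kf[idx] + k[j]
    }
    k <- kf
    center <- 1L
  }
  out <- stats::filter(m, k, method = "convolution", sides = 1,
                       circular = TRUE)
  # sides=1 aligns the last kernel tap with the output sample: shift so that
  # tap `center` is aligned instead.
  shift <- length(k) - center
  if (shift != 0) {
    idx <- ((seq_len(n) - 1 + shift) %% n) + 1
    out <- out[idx, , drop = FALSE]
  }
  a <- array(as.numeric(out), d[perm])
  aperm(a, order(perm))
}

# Monotone quantile map from uniform ranks to a standardized distribution
# with the requested skewness. Gamma family (mirrored for negative skew):
# skewness of Gamma(k) is 2/sqrt(k), so any target magnitude is attainable.
skew_quantile_map <- function(u, target_skew) {
  if (abs(target_skew) < 0.05) return(qnorm(u))
  k <- (2 / abs(target_skew))^2
  if (target_skew > 0) {
    (qgamma(u, shape = k) - k) / sqrt(k)
  } else {
    -(qgamma(1 - u, shape = k) - k) / sqrt(k)
  }
}

#' Generate one synthetic tumour volume and mask
#'
#' The ROI is an axis-aligned ellipsoid with +/-20% per-axis radius jitter.
#' Inside it, white Gaussian noise is smoothed with an isotropic Gaussian
#' kernel of width `texture_corr_length` (mm), rank-transformed through a
#' monotone skew quantile map to the target histogram skewness, discretized
#' to `hist_levels_active` intensity levels, and scaled to the HU location
#' and spread of the spec. The background is independent noise around a
#' distinct HU level. Deterministic given `(spec, shape_mm, spacing, seed)`.
#'
#' @param spec a [class_spec].
#' @param shape_mm length-3 field-of-view extents in mm.
#' @param spacing length-3 voxel spacing in mm.
#' @param seed integer seed.
#' @return A list with `volume` ([image_volume]) and `mask` ([roi_mask]).
#' @export
generate_tumor <- function(spec, shape_mm = c(40, 40, 50),
                           spacing = c(1, 1, 5), seed = 1L) {
  stopifnot(inherits(spec, "class_spec"))
  shape_mm <- as.numeric(shape_mm); spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0) || any(!is.finite(spacing)))
    stop("invalid argument: spacing must be three positive numbers",
         call. = FALSE)
  if (length(shape_mm) != 3L || any(shape_mm <= 0) || any(!is.finite(shape_mm)))
    stop("invalid argument: shape_mm must be three positive numbers",
         call. = FALSE)
  dims <- pmax(2L, as.integer(round(shape_mm / spacing)))
  withr::with_seed(sub_seed(seed, 101L), {
    # ellipsoid ROI with jittered radii (in mm)
    radii <- 0.35 * shape_mm * runif(3, 0.8, 1.2)
    centre <- shape_mm / 2
    cx <- (seq_len(dims[1]) - 0.5) * spacing[1]
    cy <- (seq_len(dims[2]) - 0.5) * spacing[2]
    cz <- (seq_len(dims[3]) - 0.5) * spacing[3]
    dx2 <- ((cx - centre[1]) / radii[1])^2
    dy2 <- ((cy - centre[2]) / radii[2])^2
    dz2 <- ((cz - centre[3]) / radii[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    if (sum(inside) < 100)
      stop("invalid argument: extents too small for a 100-voxel ROI",
           call. = FALSE)
    # correlated random field over the whole volume, so that tissue just
    # outside the contour shares the tumour's texture statistics (as
    # adjacent parenchyma does) and small contour perturbations do not
    # inject an alien intensity mode into the ROI histogram
    field <- array(rnorm(prod(dims)), dims)
    for (ax in 1:3)
      field <- smooth_axis(field, spec$texture_corr_length / spacing[ax], ax)
    v <- as.numeric(field)
    n <- length(v)
    L <- spec$hist_levels_active
    if (L == 1L) {
      hu <- rep(spec$mean_hu, n)
    } else {
      u <- (rank(v, ties.method = "first") - 0.5) / n
      x <- skew_quantile_map(u, spec$hist_skew)
      # discretize to L active levels (equal-width over the realized range)
      lev <- pmin(L, 1L + floor(L * (x - min(x)) / (max(x) - min(x))))
      centres <- min(x) + (lev - 0.5) * (max(x) - min(x)) / L
      hu <- (centres - mean(centres)) / sd(centres) * spec$sd_hu + spec$mean_hu
    }
    vol <- array(hu, dims)
    # Background: same discretized texture with attenuated contrast and
    # lower enhancement (the tumour enhances in the arterial phase), so its
    # intensity distribution is distinct from the ROI's without introducing
    # a continuum of new gray values at the contour. The enhancement
    # difference ramps over a ~2 mm sigmoidal transition, mimicking partial
    # volume at the contour; a step edge there would make small contour
    # perturbations inject a disjoint intensity mode.
    q <- outer(outer(dx2, dy2, "+"), dz2, "+")
    r_eff <- exp(mean(log(radii)))
    w <- 1 / (1 + exp(-(sqrt(q) - 1) * r_eff / 2))
    vol <- spec$mean_hu + (vol - spec$mean_hu) * (1 - 0.2 * w) - 20 * w
    if (L == 1L) vol[inside] <- spec$mean_hu  # degenerate: exactly constant
    list(volume = image_volume(vol, spacing),
         mask = roi_mask(inside, spacing))
  })
}

#' Generate one synthetic clinical record
#'
#' Informative covariates (CA 19-9, CEA, age, sex) are drawn from the
#' class-conditional distributions of the [class_spec]; the remaining
#' clinical fields are nuisance draws from class-independent defaults
#' anchored to the pooled cohort medians, so a correct screen must reject
#' them. Age is truncated to `[18, 90]`. Obesity is defined as BMI >= 25.
#'
#' @param spec a [class_spec].
#' @param seed integer seed.
#' @return One-row `data.frame` with the clinical covariate columns.
#' @export
generate_clinical <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "class_spec"))
  withr::with_seed(sub_seed(seed, 202L), {
    age <- min(90, max(18, round(rnorm(1, spec$age_mean, spec$age_sd))))
    sex <- if (runif(1) < spec$female_prob) "F" else "M"
    ca199 <- exp(rnorm(1, spec$ca199_log_mean, spec$ca199_log_sd))
    cea <- exp(rnorm(1, spec$cea_log_mean, spec$cea_log_sd))
    bmi <- rnorm(1, 23, 3)
    data.frame(
      age = age,
      sex = sex,
      location = sample(c("head-neck", "body-tail", "both"), 1,
                        prob = c(0.40, 0.53, 0.07)),
      max_diameter = exp(rnorm(1, log(3.5), 0.5)),
      ca199 = ca199,
      cea = cea,
      alt = exp(rnorm(1, log(16), 0.5)),
      ast = exp(rnorm(1, log(19), 0.4)),
      fbg = max(2.5, rnorm(1, 5.1, 1.0)),
      platelet = max(40, rnorm(1, 200, 60)),
      alb = max(20, rnorm(1, 44, 4)),
      afp = exp(rnorm(1, log(2.3), 0.6)),
      sf = exp(rnorm(1, log(130), 1.0)),
      calcification = runif(1) < 0.06,
      abdominal_symptom = runif(1) < 0.45,
      smoking = runif(1) < 0.13,
      alcohol = runif(1) < 0.17,
      obesity = bmi >= 25,
      chronic_pancreatitis = runif(1) < 0.01,
      family_history = runif(1) < 0.005,
      blood_type = sample(c("A", "B", "AB", "O"), 1,
                          prob = c(0.30, 0.17, 0.09, 0.44)),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic cohort
#'
#' Per-case sub-seeds are derived from the master seed by a counter-based
#' splitting rule (see [sub_seed()]), so the cohort is a pure function of
#' `(class_sizes, specs, seed)` and does not depend on generation order.
#'
#' @param class_sizes integer triple: cases per class, in the order of
#'   `specs` (default 76 SCA / 40 MCN / 48 IPMN).
#' @param specs named list of three [class_spec]s.
#' @param seed master integer seed.
#' @param shape_mm,spacing forwarded to [generate_tumor()].
#' @return An object of class `synthetic_cohort`: a list with `cases` (each
#'   holding `patient_id`, `volume`, `mask`, `clinical`, `label`), `labels`,
#'   `seed`, and `class_specs`.
#' @export
generate_cohort <- function(class_sizes = c(76, 40, 48),
                            specs = default_class_specs(),
                            seed = 1L,
                            shape_mm = c(40, 40, 50),
                            spacing = c(1, 1, 5)) {
  class_sizes <- as.integer(class_sizes)
  if (length(class_sizes) != length(specs) || any(class_sizes < 1))
    stop("class_sizes must give a positive count per spec", call. = FALSE)
  cases <- list()
  idx <- 0L
  for (ci in seq_along(specs)) {
    spec <- specs[[ci]]
    for (k in seq_len(class_sizes[ci])) {
      idx <- idx + 1L
      case_seed <- sub_seed(seed, ci, k)
      tm <- generate_tumor(spec, shape_mm = shape_mm, spacing = spacing,
                           seed = case_seed)
      cl <- generate_clinical(spec, seed = case_seed)
      cases[[idx]] <- list(patient_id = sprintf("P%03d", idx),
                           volume = tm$volume, mask = tm$mask,
                           clinical = cl, label = spec$label)
    }
  }
  structure(list(cases = cases,
                 labels = vapply(cases, `[[`, character(1), "label"),
                 seed = as.integer(seed),
                 class_specs = specs),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases (%s), seed %d\n",
              length(x$cases),
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = ", "),
              x$seed))
  invisible(x)
}

#' Clinical covariate table of a cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @return `data.frame` with `patient_id`, the clinical columns, and `label`.
#' @export
clinical_table <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tabs <- lapply(cohort$cases, function(cs)
    cbind(data.frame(patient_id = cs$patient_id, stringsAsFactors = FALSE),
          cs$clinical,
          data.frame(label = cs$label, stringsAsFactors = FALSE)))
  do.call(rbind, tabs)
}

#' Write a cohort to disk (NIfTI volumes/masks, clinical CSV, manifest)
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$cases, function(cs) {
    vp <- file.path(dir, paste0(cs$patient_id, "_vol.nii.gz"))
    mp <- file.path(dir, paste0(cs$patient_id, "_mask.nii.gz"))
    write_case(cs$volume, cs$mask, vp, mp)
    list(patient_id = cs$patient_id, volume = basename(vp),
         mask = basename(mp), label = cs$label)
  })
  ct <- clinical_table(cohort)
  utils::write.csv(ct, file.path(dir, "clinical.csv"), row.names = FALSE)
  manifest <- list(n_cases = length(cohort$cases), seed = cohort$seed,
                   clinical = "clinical.csv", cases = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
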