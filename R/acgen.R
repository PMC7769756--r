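#' Attenuation map container
#'
#' A `mu_map` wraps a 3D volume of linear attenuation coefficients at 511 keV
#' (cm^-1) together with the method that produced it. Values must lie in
#' \[0, 0.5\] cm^-1.
#'
#' @param mu_volume 3D array of attenuation coefficients (cm^-1).
#' @param method_tag one of `"TRUTH"`, `"GE_REF"`, `"ATLAS1"`, `"MAXPROB"`,
#'   `"ZTE"`.
#' @param provenance optional list snapshotting the generating parameters.
#' @export
mu_map <- function(mu_volume, method_tag = "TRUTH", provenance = list()) {
  method_tag <- match.arg(method_tag,
                          c("TRUTH", "GE_REF", "ATLAS1", "MAXPROB", "ZTE"))
  if (any(!is.finite(mu_volume))) stop("mu_volume contains non-finite values")
  if (min(mu_volume) < 0 || max(mu_volume) > 0.5) {
    stop("attenuation coefficients must lie in [0, 0.5] cm^-1")
  }
  structure(
    list(mu_volume = mu_volume, method_tag = method_tag,
         provenance = provenance),
    class = "mu_map"
  )
}

as_mu_volume <- function(x) {
  if (inherits(x, "mu_map")) x$mu_volume else x
}

#' @export
print.mu_map <- function(x, ...) {
  cat(sprintf("<mu_map:%s> range [%.4f, %.4f] cm^-1\n",
              x$method_tag, min(x$mu_volume), max(x$mu_volume)))
  invisible(x)
}

# Tissue class codes used by the voting stage.
CLASS_AIR <- 0L
CLASS_SOFT <- 1L
CLASS_BONE <- 2L

#' Threshold-based CT tissue classification
#'
#' Segments a CT volume into air, soft tissue and bone by intensity
#' thresholds: air below `air_upper` HU, bone above `bone_lower` HU, soft
#' tissue on the closed interval in between (boundary values are soft
#' tissue).
#'
#' @param ct HU volume (array).
#' @param air_upper,bone_lower class thresholds in HU; defaults -500 and 300.
#' @return object of class `tissue_class_volume`: `class_volume` (integer
#'   array, 0 air / 1 soft / 2 bone) and the thresholds used.
#' @export
classify_tissue <- function(ct, air_upper = -500, bone_lower = 300) {
  if (air_upper >= bone_lower) stop("thresholds must satisfy air_upper < bone_lower")
  if (any(!is.finite(ct))) stop("CT volume contains non-finite HU values")
  cls <- array(CLASS_SOFT, dim(ct))
  cls[ct < air_upper] <- CLASS_AIR
  cls[ct > bone_lower] <- CLASS_BONE
  structure(
    list(class_volume = cls,
         thresholds = c(air_upper = air_upper, bone_lower = bone_lower)),
    class = "tissue_class_volume"
  )
}

#' Bilinear HU to 511 keV attenuation conversion
#'
#' The calibration is the piecewise-linear function through (-1000 HU, 0)
#' and (`breakpoint`, `mu_water`), continuing above the breakpoint with
#' `slope_above`. It is continuous at the breakpoint and nondecreasing.
#'
#' @param mu_water attenuation of water at 511 keV (cm^-1).
#' @param breakpoint HU at which the slope changes (water point).
#' @param slope_above cm^-1 per HU above the breakpoint; the default maps
#'   1000 HU to 0.130 cm^-1.
#' @return object of class `bilinear_calibration`.
#' @export
bilinear_calibration <- function(mu_water = 0.096, breakpoint = 0,
                                 slope_above = (0.130 - 0.096) / 1000) {
  slope_below <- mu_water / (breakpoint + 1000)
  if (mu_water <= 0 || breakpoint <= -1000) {
    stop("calibration requires mu_water > 0 and breakpoint > -1000 HU")
  }
  if (slope_above < 0) stop("calibration must be nondecreasing")
  structure(
    list(mu_water = mu_water, breakpoint = breakpoint,
         slope_below = slope_below, slope_above = slope_above),
    class = "bilinear_calibration"
  )
}

#' @rdname bilinear_calibration
#' @param ct HU volume.
#' @param cal a `bilinear_calibration`.
#' @param method_tag tag stored on the returned [mu_map()].
#' @export
hu_to_mu_bilinear <- function(ct, cal = bilinear_calibration(),
                              method_tag = "TRUTH") {
  if (any(!is.finite(ct))) stop("CT volume contains non-finite HU values")
  d <- ct - cal$breakpoint
  mu <- cal$mu_water + ifelse(d <= 0, cal$slope_below, cal$slope_above) * d
  mu <- pmax(mu, 0)
  dim(mu) <- dim(ct)
  mu_map(mu, method_tag,
         provenance = list(calibration = unclass(cal)))
}

# --- multi-atlas pseudo-CT --------------------------------------------------

# Register one atlas pair onto the target grid. Oracle mode uses the stored
# true inverse displacement; affine mode estimates a translation by
# centre-of-mass alignment of the MR channel.
register_atlas <- function(pair, target_mr, mode, similarity_floor = 0.5) {
  dm <- dim(pair$ct)
  if (mode == "oracle") {
    inv <- pair$transform$inv_disp
  } else {
    com <- function(v) {
      w <- pmax(v - stats::quantile(v, 0.5), 0)
      idx <- coord_index_grids(dim(v))
      c(sum(idx$x * w), sum(idx$y * w), sum(idx$z * w)) / sum(w)
    }
    shift <- com(pair$mr) - com(target_mr)
    inv <- array(0, c(dm, 3))
    for (d in 1:3) inv[, , , d] <- shift[d]
  }
  mr_reg <- apply_displacement(pair$mr, inv)
  cc <- suppressWarnings(stats::cor(as.vector(mr_reg), as.vector(target_mr)))
  if (!is.finite(cc) || cc < similarity_floor) {
    stop(sprintf("registration failed for %s (similarity %.2f below %.2f)",
                 pair$id, ifelse(is.finite(cc), cc, NA), similarity_floor))
  }
  apply_displacement(pair$ct, inv)
}

#' Multi-atlas pseudo-CT by majority voting
#'
#' Registers every atlas CT to the target, classifies each registered CT into
#' air / soft tissue / bone, assigns each voxel the majority tissue class
#' across the database, and sets the pseudo-CT value to the mean HU over the
#' atlases belonging to the majority class at that voxel. With a single atlas
#' this degenerates to that atlas's registered CT (the single-atlas
#' emulation). Vote ties are resolved by the fixed priority
#' soft > bone > air.
#'
#' @param target_mr target T1-like volume (defines the grid).
#' @param atlas_db list of atlas pairs from [make_atlas_database()].
#' @param registration_mode `"oracle"` (use stored true transforms) or
#'   `"affine"` (centre-of-mass translation estimate).
#' @param air_upper,bone_lower classification thresholds (HU).
#' @return pseudo-CT volume (HU array) with attribute `"class_volume"`.
#' @export
maxprob_pseudo_ct <- function(target_mr, atlas_db,
                              registration_mode = c("oracle", "affine"),
                              air_upper = -500, bone_lower = 300) {
  registration_mode <- match.arg(registration_mode)
  if (length(atlas_db) == 0) stop("atlas database is empty")
  dm <- dim(atlas_db[[1]]$ct)
  counts <- list(air = array(0, dm), soft = array(0, dm), bone = array(0, dm))
  sums <- list(air = array(0, dm), soft = array(0, dm), bone = array(0, dm))
  for (pair in atlas_db) {
    ct_reg <- register_atlas(pair, target_mr, registration_mode)
    cls <- classify_tissue(ct_reg, air_upper, bone_lower)$class_volume
    for (k in c(CLASS_AIR, CLASS_SOFT, CLASS_BONE)) {
      nm <- c("air", "soft", "bone")[k + 1L]
      sel <- cls == k
      counts[[nm]] <- counts[[nm]] + sel
      sums[[nm]] <- sums[[nm]] + ct_reg * sel
    }
  }
  # majority vote with tie priority soft > bone > air
  cls <- array(CLASS_AIR, dm)
  soft_wins <- counts$soft >= counts$bone & counts$soft >= counts$air
  bone_wins <- !soft_wins & counts$bone >= counts$air
  cls[soft_wins] <- CLASS_SOFT
  cls[bone_wins] <- CLASS_BONE
  pseudo <- array(-1000, dm)
  for (k in c(CLASS_AIR, CLASS_SOFT, CLASS_BONE)) {
    nm <- c("air", "soft", "bone")[k + 1L]
    sel <- cls == k & counts[[nm]] > 0
    pseudo[sel] <- sums[[nm]][sel] / counts[[nm]][sel]
  }
  attr(pseudo, "class_volume") <- cls
  pseudo
}

# --- ZTE-like segmentation --------------------------------------------------

#' ZTE intensity to HU calibration line
#'
#' Two anchor points `(normalized intensity, HU)` define the continuous bone
#' calibration: denser bone gives less proton-density signal, so HU decreases
#' with intensity. Soft tissue receives a fixed attenuation coefficient.
#'
#' @param anchor1,anchor2 numeric length-2 vectors `(intensity, HU)`; the
#'   defaults invert the phantom's bone intensity model
#'   (`zte = 0.55 - 1e-4 * HU`).
#' @param soft_tissue_mu fixed soft-tissue coefficient, 0.100 cm^-1 as used
#'   by segmentation-based clinical attenuation correction.
#' @export
zte_calibration <- function(anchor1 = c(0.55, 0), anchor2 = c(0.45, 1000),
                            soft_tissue_mu = 0.100) {
  if (anchor1[1] == anchor2[1]) stop("calibration anchors must differ in intensity")
  structure(
    list(anchor1 = anchor1, anchor2 = anchor2,
         slope = (anchor2[2] - anchor1[2]) / (anchor2[1] - anchor1[1]),
         soft_tissue_mu = soft_tissue_mu),
    class = "zte_calibration"
  )
}

zte_intensity_to_hu <- function(x, cal) {
  cal$anchor1[2] + cal$slope * (x - cal$anchor1[1])
}

# Fit a Gaussian to the main histogram peak of `values` by a quadratic fit to
# log-counts around the mode. Returns c(mode, sigma).
fit_main_peak <- function(values, n_bins = 128L) {
  h <- graphics::hist(values, breaks = n_bins, plot = FALSE)
  if (all(h$counts == 0)) stop("histogram has no detectable main peak")
  pk <- which.max(h$counts)
  win <- max(1L, pk - 4L):min(length(h$counts), pk + 4L)
  win <- win[h$counts[win] > 0]
  if (length(win) < 3) {
    # degenerate (near-delta) peak: sigma from bin width
    return(c(mode = h$mids[pk], sigma = diff(h$breaks[1:2]) / 2))
  }
  x <- h$mids[win]
  y <- log(h$counts[win])
  fit <- stats::lm(y ~ x + I(x^2))
  a <- stats::coef(fit)[[3]]
  if (!is.finite(a) || a >= 0) {
    return(c(mode = h$mids[pk], sigma = stats::sd(values[abs(values - h$mids[pk]) <
                                                           4 * diff(h$breaks[1:2])])))
  }
  sigma <- sqrt(-1 / (2 * a))
  mode <- -stats::coef(fit)[[2]] / (2 * a)
  c(mode = mode, sigma = sigma)
}

#' Histogram-based ZTE-like attenuation map
#'
#' Emulates segmentation of a zero-echo-time MR image into a continuous-bone
#' attenuation map: intensities inside the head mask are normalized to the
#' soft-tissue histogram mode, log-rescaled to enhance the bone band, and a
#' Gaussian is fitted to the main (soft tissue) peak. Voxels falling in the
#' sub-peak band `[mode - band_lo * sigma, mode - band_hi * sigma]` are
#' labelled bone and receive continuous coefficients through the
#' intensity-to-HU calibration line followed by bilinear HU conversion.
#' In-mask voxels below the bone band are internal air (0); all remaining
#' in-mask voxels receive the fixed soft-tissue coefficient.
#'
#' Because the fitted peak width collapses in the noise-free limit, the band
#' width uses `sigma_eff = max(sigma, sigma_floor)` on the log scale.
#'
#' @param zte nonnegative intensity volume.
#' @param head_mask logical array of in-head voxels.
#' @param cal a [zte_calibration()].
#' @param band_lo,band_hi bone band in units of sigma below the mode.
#' @param sigma_floor minimum effective log-scale sigma.
#' @param bilinear a [bilinear_calibration()] for the bone HU conversion.
#' @return a [mu_map()] with tag `"ZTE"`.
#' @export
zte_like_segment <- function(zte, head_mask, cal = zte_calibration(),
                             band_lo = 4, band_hi = 1.5, sigma_floor = 0.35,
                             bilinear = bilinear_calibration()) {
  if (any(zte < 0)) stop("ZTE intensities must be nonnegative")
  if (!any(head_mask)) stop("head mask is empty")
  vals <- zte[head_mask]
  pk <- fit_main_peak(vals)
  if (!is.finite(pk[["mode"]]) || pk[["mode"]] <= 0) {
    stop("histogram has no detectable main peak")
  }
  norm <- zte / pk[["mode"]]
  eps <- 1e-6
  logi <- log(pmax(norm, eps))
  lpk <- fit_main_peak(logi[head_mask & norm > 0.5])
  sigma_eff <- max(lpk[["sigma"]], sigma_floor)
  lo <- lpk[["mode"]] - band_lo * sigma_eff
  hi <- lpk[["mode"]] - band_hi * sigma_eff

  mu <- array(0, dim(zte))
  soft_sel <- head_mask
  bone_sel <- head_mask & logi >= lo & logi <= hi
  air_sel <- head_mask & logi < lo  # internal air: second histogram threshold
  mu[soft_sel] <- cal$soft_tissue_mu
  mu[air_sel] <- 0
  if (any(bone_sel)) {
    hu <- zte_intensity_to_hu(norm[bone_sel], cal)
    mu[bone_sel] <- hu_to_mu_bilinear(hu, bilinear)$mu_volume
  }
  mu_map(pmin(pmax(mu, 0), 0.5), "ZTE",
         provenance = list(band = c(lo = lo, hi = hi),
                           sigma_eff = sigma_eff,
                           calibration = unclass(cal)))
}

#' Degraded transmission-like reference attenuation map
#'
#' Emulates the resolution and noise character of a transmission-measured
#' reference map by Gaussian smoothing of the ground-truth map followed by
#' additive Gaussian noise, clipped at zero.
#'
#' @param truth_mu a [mu_map()] or bare array (cm^-1).
#' @param psf_fwhm smoothing kernel FWHM in mm.
#' @param noise_sd additive noise SD in cm^-1.
#' @param seed integer seed (deterministic output per seed).
#' @param voxel_size mm per axis.
#' @return a [mu_map()] with tag `"GE_REF"`.
#' @export
degrade_to_reference <- function(truth_mu, psf_fwhm = 6, noise_sd = 0.004,
                                 seed = 1L, voxel_size = c(3, 3, 3)) {
  if (psf_fwhm < 0 || noise_sd < 0) stop("psf_fwhm and noise_sd must be >= 0")
  vol <- as_mu_volume(truth_mu)
  sm <- gaussian_smooth3(vol, rep(psf_fwhm, 3), voxel_size)
  out <- with_seed(seed, {
    if (noise_sd > 0) sm + rnorm(length(sm), 0, noise_sd) else sm
  })
  out <- array(pmin(pmax(out, 0), 0.5), dim(vol))
  mu_map(out, "GE_REF",
         provenance = list(psf_fwhm = psf_fwhm, noise_sd = noise_sd,
                           seed = seed))
}
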