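#' Reference-region input curve
#'
#' Biexponential bolus shape `C_R(t) = A (exp(-beta1 t) - exp(-beta2 t))`
#' used as the simulated cerebellar reference curve. It starts at zero,
#' peaks within a few minutes and decays slowly, and admits closed-form
#' convolutions with exponentials, which the test oracles exploit.
#'
#' @param A amplitude (kBq/mL); @param beta1,beta2 rate constants (min^-1).
#' @return a function of time in minutes.
#' @export
reference_input <- function(A = 30, beta1 = 0.03, beta2 = 0.6) {
  force(A); force(beta1); force(beta2)
  function(t_min) A * (exp(-beta1 * t_min) - exp(-beta2 * t_min))
}

# Dense time grid (minutes) covering a schedule with step dt_s seconds.
dense_grid <- function(schedule, dt_s = 0.25) {
  end_s <- max(schedule$start + schedule$duration)
  seq(0, end_s, by = dt_s) / 60
}

# Evaluate a reference specification (function, or list(t_min, value) for a
# measured curve, linearly interpolated with C_R(0) = 0) on a dense grid.
eval_reference <- function(reference, t_min) {
  if (is.function(reference)) return(reference(t_min))
  if (is.list(reference) && !is.null(reference$t_min)) {
    tt <- c(0, reference$t_min)
    vv <- c(0, reference$value)
    return(approx(tt, vv, xout = t_min, rule = 2)$y)
  }
  stop("reference must be a function of minutes or a list(t_min, value)")
}

# Convolution (cr * exp(-theta t)) on an equispaced grid, exact for
# piecewise-linear cr: per-segment closed form accumulated by a first-order
# recursive filter.
conv_exp <- function(cr, h, theta) {
  n <- length(cr)
  E <- exp(-theta * h)
  c1 <- (1 - E) / theta
  c2 <- h / theta - (1 - E) / theta^2
  a <- cr[-n]
  b <- (cr[-1] - cr[-n]) / h
  u <- a * c1 + b * c2
  y <- stats::filter(u, E, method = "recursive", init = 0)
  c(0, as.numeric(y))
}

# Frame-averaged values of a densely sampled curve. The dense step must
# divide the frame boundaries (trapezoidal average within each frame).
frame_average <- function(dense, t_min, schedule) {
  dt_min <- t_min[2] - t_min[1]
  vapply(seq_len(nframes(schedule)), function(f) {
    i0 <- round(schedule$start[f] / 60 / dt_min) + 1L
    i1 <- round((schedule$start[f] + schedule$duration[f]) / 60 / dt_min) + 1L
    if (i1 > length(dense)) stop("schedule extends beyond reference support")
    (sum(dense[i0:i1]) - (dense[i0] + dense[i1]) / 2) * dt_min /
      (schedule$duration[f] / 60)
  }, numeric(1))
}

#' Time-activity curve container
#'
#' @param value frame-averaged activity (kBq/mL).
#' @param schedule a [frame_schedule()].
#' @param suv optional standardized uptake values.
#' @export
tac <- function(value, schedule, suv = NULL) {
  if (length(value) != nframes(schedule)) {
    stop("TAC length must match the frame schedule")
  }
  structure(
    list(time_min = schedule$mid_min, value = as.numeric(value),
         duration_min = schedule$duration_min, schedule = schedule,
         suv = suv),
    class = "tac"
  )
}

#' Simplified reference tissue model forward prediction
#'
#' Computes the target-tissue curve
#' `C_T(t) = R1 C_R(t) + (k2 - R1 k2a) (C_R * exp(-k2a t))(t)`
#' on a dense grid (exact convolution for piecewise-linear `C_R`) and
#' averages it over the acquisition frames.
#'
#' @param params named vector or list with `R1`, `k2`, `k2a` (rates min^-1).
#' @param reference reference curve: a function of minutes (e.g.
#'   [reference_input()]) or a measured `list(t_min, value)`.
#' @param schedule a [frame_schedule()].
#' @param dt_s dense quadrature step in seconds (<= 1 s).
#' @return a [tac()].
#' @export
srtm_forward <- function(params, reference, schedule = default_frame_schedule(),
                         dt_s = 0.25) {
  R1 <- params[["R1"]]; k2 <- params[["k2"]]; k2a <- params[["k2a"]]
  if (k2 <= 0 || k2a <= 0) stop("rates k2 and k2a must be > 0")
  if (dt_s > 1) stop("dense step must be <= 1 s for accurate quadrature")
  t_min <- dense_grid(schedule, dt_s)
  cr <- eval_reference(reference, t_min)
  conv <- conv_exp(cr, t_min[2] - t_min[1], k2a)
  ct <- R1 * cr + (k2 - R1 * k2a) * conv
  tac(frame_average(ct, t_min, schedule), schedule)
}

#' Basis set for receptor parametric mapping
#'
#' Precomputes frame-averaged basis curves `B_i = C_R * exp(-theta_i t)` on a
#' log-spaced grid of washout rates, together with the normal-equation terms
#' used by the linearized SRTM fit.
#'
#' @inheritParams srtm_forward
#' @param theta_min,theta_max washout-rate range (min^-1).
#' @param n_theta number of basis functions.
#' @return object of class `basis_set` with fields `theta`, `B`
#'   (frames x n_theta), `cr_frames`, and cached solver terms.
#' @export
make_basis <- function(reference, schedule = default_frame_schedule(),
                       theta_min = 0.01, theta_max = 0.6, n_theta = 100,
                       dt_s = 0.25) {
  if (theta_min <= 0 || theta_max <= theta_min) {
    stop("need 0 < theta_min < theta_max")
  }
  if (n_theta < 2) stop("n_theta must be >= 2")
  theta <- exp(seq(log(theta_min), log(theta_max), length.out = n_theta))
  t_min <- dense_grid(schedule, dt_s)
  cr <- eval_reference(reference, t_min)
  # a measured (frame-averaged) reference enters the design directly; the
  # dense interpolant is only used to form the convolution basis
  cr_frames <- if (is.list(reference) &&
                   length(reference$value) == nframes(schedule)) {
    as.numeric(reference$value)
  } else {
    frame_average(cr, t_min, schedule)
  }
  h <- t_min[2] - t_min[1]
  B <- vapply(theta, function(th) {
    frame_average(conv_exp(cr, h, th), t_min, schedule)
  }, numeric(nframes(schedule)))
  # cached least-squares terms for the design [cr_frames, B_i]
  cc <- sum(cr_frames^2)
  cb <- colSums(cr_frames * B)
  bb <- colSums(B^2)
  structure(
    list(theta = theta, B = B, cr_frames = cr_frames, schedule = schedule,
         cc = cc, cb = cb, bb = bb),
    class = "basis_set"
  )
}

# Vectorized linearized-SRTM fit. Y: frames x nvox matrix. Returns list of
# per-voxel vectors R1, k2, k2a, BP_ND, rss, theta_index. For each candidate
# theta the two-parameter least squares C_T ~ R1 C_R + phi B_i is solved in
# closed form; fits with k2 < 0 are refit under the boundary constraint
# k2 = 0 (BP_ND = -1) so BP_ND never falls below -1. The theta with minimal
# RSS wins; RSS ties resolve to the smaller theta.
rpm_fit_matrix <- function(Y, basis) {
  if (all(abs(basis$cr_frames) < 1e-12)) {
    stop("degenerate design: reference curve is identically zero")
  }
  nvox <- ncol(Y)
  yty <- colSums(Y^2)
  cy <- as.numeric(crossprod(basis$cr_frames, Y))  # per-voxel <C_R, y>
  best <- list(
    rss = rep(Inf, nvox), R1 = rep(NA_real_, nvox), k2 = rep(NA_real_, nvox),
    theta = rep(NA_real_, nvox), idx = rep(NA_integer_, nvox)
  )
  for (i in seq_along(basis$theta)) {
    th <- basis$theta[i]
    b <- basis$B[, i]
    by <- as.numeric(crossprod(b, Y))
    det <- basis$cc * basis$bb[i] - basis$cb[i]^2
    if (det <= 1e-12 * basis$cc * basis$bb[i] + 1e-300) next
    R1 <- (basis$bb[i] * cy - basis$cb[i] * by) / det
    phi <- (basis$cc * by - basis$cb[i] * cy) / det
    rss <- yty - (R1 * cy + phi * by)
    k2 <- phi + R1 * th
    # boundary-constrained refit where k2 < 0: C_T ~ R1 (C_R - theta B_i)
    neg <- which(k2 < 0)
    if (length(neg) > 0) {
      w_ww <- basis$cc - 2 * th * basis$cb[i] + th^2 * basis$bb[i]
      wy <- cy[neg] - th * by[neg]
      R1c <- wy / w_ww
      rss[neg] <- yty[neg] - wy^2 / w_ww
      R1[neg] <- R1c
      k2[neg] <- 0
    }
    take <- rss < best$rss
    if (any(take)) {
      best$rss[take] <- rss[take]
      best$R1[take] <- R1[take]
      best$k2[take] <- k2[take]
      best$theta[take] <- th
      best$idx[take] <- i
    }
  }
  list(
    R1 = best$R1, k2 = best$k2, k2a = best$theta,
    BP_ND = best$k2 / best$theta - 1, rss = pmax(best$rss, 0),
    theta_index = best$idx
  )
}

#' Fit the simplified reference tissue model by basis functions
#'
#' Linearized SRTM (receptor parametric mapping): for each candidate washout
#' rate theta the model `C_T ~ R1 C_R + phi B_theta` is a linear least
#' squares; the theta minimizing the residual sum of squares is selected and
#' the parameters recovered as `k2 = phi + R1 theta`, `k2a = theta`,
#' `BP_ND = k2 / k2a - 1`.
#'
#' @param target a [tac()] sharing the basis schedule.
#' @param basis a [make_basis()] result.
#' @return object of class `srtm_fit` with `R1`, `k2`, `k2a`, `BP_ND`,
#'   `rss`, `theta_index`.
#' @export
rpm_fit <- function(target, basis) {
  stopifnot_same_schedule(target$schedule, basis$schedule)
  res <- rpm_fit_matrix(matrix(target$value, ncol = 1), basis)
  structure(lapply(res, function(v) v[[1]]), class = "srtm_fit")
}

#' @export
print.srtm_fit <- function(x, ...) {
  cat(sprintf("<srtm_fit> R1 = %.4f, k2 = %.4f min^-1, BP_ND = %.4f\n",
              x$R1, x$k2, x$BP_ND))
  invisible(x)
}

#' Dynamic image container
#'
#' 4D activity (kBq/mL) with its frame schedule, subject id and the
#' attenuation-correction method used at reconstruction.
#'
#' @param data 4D array (x, y, z, frame).
#' @param schedule a [frame_schedule()].
#' @param subject_id,ac_method identifying tags.
#' @export
dynamic_image <- function(data, schedule, subject_id = "sim",
                          ac_method = "TRUTH") {
  if (dim(data)[4] != nframes(schedule)) {
    stop("frame count of data must match the schedule")
  }
  structure(
    list(data = data, schedule = schedule, subject_id = subject_id,
         ac_method = ac_method),
    class = "dynamic_image"
  )
}

#' @export
print.dynamic_image <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("<dynamic_image:%s/%s> %dx%dx%d voxels, %d frames\n",
              x$subject_id, x$ac_method, dm[1], dm[2], dm[3], dm[4]))
  invisible(x)
}

#' Noise-free dynamic activity from kinetic ground truth
#'
#' Evaluates the SRTM forward model for every region of a phantom and paints
#' the frame-averaged curves into a 4D volume (zero outside labelled
#' regions unless `background_soft` assigns unlabelled soft tissue the
#' white-matter curve).
#'
#' @param phantom a [make_phantom()] result.
#' @param truth a [assign_kinetics()] table.
#' @param schedule a [frame_schedule()].
#' @param reference reference input curve (function of minutes).
#' @param background_soft region name whose curve fills unlabelled soft
#'   tissue (default "white-matter"; NULL leaves it at zero).
#' @return a [dynamic_image()] with `ac_method = "TRUTH"`.
#' @export
true_dynamic_from_truth <- function(phantom, truth,
                                    schedule = default_frame_schedule(),
                                    reference = reference_input(),
                                    background_soft = "white-matter") {
  rl <- region_labels()
  dm <- dim(phantom$region_map)
  nf <- nframes(schedule)
  data <- array(0, c(dm, nf))
  curves <- lapply(seq_len(nrow(truth)), function(i) {
    srtm_forward(truth[i, c("R1", "k2", "k2a")], reference, schedule)$value
  })
  names(curves) <- truth$region
  region <- phantom$region_map
  if (!is.null(background_soft)) {
    region[phantom$label_volume == LABEL_SOFT & region == rl[["none"]]] <-
      rl[[background_soft]]
  }
  for (nm in names(curves)) {
    sel <- which(region == rl[[nm]])
    if (length(sel) == 0) next
    for (f in seq_len(nf)) {
      plane <- data[, , , f]
      plane[sel] <- curves[[nm]][f]
      data[, , , f] <- plane
    }
  }
  dynamic_image(data, schedule, ac_method = "TRUTH")
}

#' Voxel-wise parametric maps by receptor parametric mapping
#'
#' Builds the reference curve as the mean TAC over the reference region,
#' constructs the basis set, and fits every voxel inside the brain mask.
#'
#' @param dynamic a [dynamic_image()].
#' @param reference_voi logical array marking cerebellar reference voxels.
#' @param brain_mask logical array of voxels to fit.
#' @param theta_min,theta_max,n_theta basis configuration.
#' @return list with 3D arrays `R1` and `BP_ND` (0 outside the mask) and the
#'   fitted `basis`.
#' @export
fit_parametric_maps <- function(dynamic, reference_voi, brain_mask,
                                theta_min = 0.01, theta_max = 0.6,
                                n_theta = 100) {
  if (!any(brain_mask)) stop("brain mask is empty")
  if (!any(reference_voi & brain_mask)) {
    stop("reference VOI is empty within the brain mask")
  }
  ref_tac <- extract_tac(dynamic, reference_voi)
  basis <- make_basis(list(t_min = ref_tac$time_min, value = ref_tac$value),
                      dynamic$schedule, theta_min, theta_max, n_theta)
  idx <- which(brain_mask)
  nf <- nframes(dynamic$schedule)
  Y <- matrix(0, nf, length(idx))
  for (f in seq_len(nf)) {
    plane <- dynamic$data[, , , f]
    Y[f, ] <- plane[idx]
  }
  fit <- rpm_fit_matrix(Y, basis)
  mk <- function(v) {
    out <- array(0, dim(brain_mask))
    out[idx] <- v
    out
  }
  list(R1 = mk(fit$R1), BP_ND = mk(fit$BP_ND), basis = basis)
}

#' Extract a regional time-activity curve
#'
#' @param dynamic a [dynamic_image()].
#' @param voi logical array (or integer indices) of voxels to average.
#' @return a [tac()] of frame-wise means over the VOI.
#' @export
extract_tac <- function(dynamic, voi) {
  idx <- if (is.logical(voi)) which(voi) else as.integer(voi)
  if (length(idx) == 0) stop("VOI is empty")
  nf <- nframes(dynamic$schedule)
  v <- vapply(seq_len(nf), function(f) {
    plane <- dynamic$data[, , , f]
    mean(plane[idx])
  }, numeric(1))
  tac(v, dynamic$schedule)
}

#' Standardized uptake values
#'
#' SUV = activity (kBq/mL) divided by injected dose per body weight
#' (MBq/kg), assuming tissue density 1 g/mL; with the default 5 MBq/kg an
#' activity of 10 kBq/mL gives SUV 2.
#'
#' @param x a [tac()].
#' @param dose_per_kg injected dose per body weight (MBq/kg).
#' @return the TAC with its `suv` field populated.
#' @export
to_suv <- function(x, dose_per_kg = 5) {
  if (dose_per_kg <= 0) stop("dose_per_kg must be > 0")
  x$suv <- x$value / dose_per_kg
  x
}

#' Poisson-like counting noise on a time-activity curve
#'
#' Adds frame-wise noise consistent with Poisson counting statistics: the
#' expected counts in a frame are proportional to activity, frame duration
#' and the frame-averaged radioactive decay factor, so early short frames
#' and late (decayed) frames are noisier.
#'
#' @param x a [tac()].
#' @param counts_per_kbq_s expected counts per (kBq/mL x s) for the region.
#' @param half_life isotope half-life in minutes (default carbon-11).
#' @param seed integer seed.
#' @return a [tac()] with noisy values.
#' @export
tac_poisson_noise <- function(x, counts_per_kbq_s = 20, half_life = 20.36,
                              seed = 1L) {
  dec <- decay_factors(x$schedule, half_life)
  expected <- pmax(x$value, 0) * x$schedule$duration * dec * counts_per_kbq_s
  noisy <- with_seed(seed, rpois(length(expected), expected))
  v <- ifelse(expected > 0,
              noisy / (x$schedule$duration * dec * counts_per_kbq_s), 0)
  tac(v, x$schedule, suv = x$suv)
}

# Frame-averaged decay factors exp(-lambda t) for a schedule (times in s,
# half-life in min).
decay_factors <- function(schedule, half_life) {
  lam <- log(2) / (half_life * 60)  # s^-1
  t1 <- schedule$start
  t2 <- schedule$start + schedule$duration
  (exp(-lam * t1) - exp(-lam * t2)) / (lam * (t2 - t1))
}
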