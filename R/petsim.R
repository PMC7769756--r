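#' Acquisition model for the 2D parallel-beam PET simulation
#'
#' Holds the sinogram geometry and counting model used to propagate
#' attenuation-map errors into reconstructed activity. Expected counts per
#' sinogram bin are `counts_scale * frame_duration_s * decay_factor *
#' ACF * line_integral(activity)`, with line integrals in kBq/mL x mm.
#'
#' @param n_angles projection angles over half a turn.
#' @param n_bins radial bins.
#' @param bin_width bin spacing in mm (NULL derives it from the image grid so
#'   the detector covers the field of view).
#' @param counts_scale expected counts per (kBq/mL x mm x s) per ray.
#' @param half_life isotope half-life in minutes (carbon-11 default).
#' @param decay_correct correct reconstructed activity back to injection
#'   time (standard convention for dynamic PET feeding kinetic models).
#' @param step_frac ray sampling step as a fraction of the pixel size.
#' @export
acquisition_model <- function(n_angles = 120, n_bins = 96, bin_width = NULL,
                              counts_scale = 0.001, half_life = 20.36,
                              decay_correct = TRUE, step_frac = 0.5) {
  if (half_life <= 0) stop("half_life must be > 0")
  if (counts_scale < 0) stop("counts_scale must be >= 0")
  structure(
    list(n_angles = as.integer(n_angles), n_bins = as.integer(n_bins),
         bin_width = bin_width, counts_scale = counts_scale,
         half_life = half_life, decay_correct = decay_correct,
         step_frac = step_frac),
    class = "acquisition_model"
  )
}

resolve_geometry <- function(model, n, pixel_size) {
  bw <- model$bin_width
  if (is.null(bw)) bw <- n * pixel_size / model$n_bins
  list(n = n, nang = model$n_angles, nbins = model$n_bins, bw = bw,
       p = pixel_size, step = model$step_frac * pixel_size)
}

#' Parallel-beam forward projection of an image slice
#'
#' Discrete line integrals (value x mm) along parallel rays for each angle,
#' computed by ray-driven sampling with bilinear interpolation.
#'
#' @param image_slice square matrix.
#' @param model an [acquisition_model()].
#' @param pixel_size pixel edge length in mm.
#' @return sinogram matrix (`n_bins` x `n_angles`).
#' @export
forward_project <- function(image_slice, model = acquisition_model(),
                            pixel_size = 3) {
  if (nrow(image_slice) != ncol(image_slice)) stop("image slice must be square")
  g <- resolve_geometry(model, nrow(image_slice), pixel_size)
  cpp_forward_project(image_slice, g$nang, g$nbins, g$bw, g$p, g$step)
}

#' @rdname forward_project
#' @param sinogram matrix (`n_bins` x `n_angles`).
#' @param n image size in pixels.
#' @export
back_project <- function(sinogram, n, model = acquisition_model(),
                         pixel_size = 3) {
  g <- resolve_geometry(model, n, pixel_size)
  cpp_back_project(sinogram, g$n, g$bw, g$p, g$step)
}

#' Attenuation correction factors along each ray
#'
#' Per ray, `exp(-integral of mu dl)` with the attenuation coefficients in
#' cm^-1 and path lengths converted from mm to cm; values lie in (0, 1].
#'
#' @param mu_slice attenuation slice (cm^-1), square matrix.
#' @inheritParams forward_project
#' @return matrix of factors (`n_bins` x `n_angles`).
#' @export
attenuation_factors <- function(mu_slice, model = acquisition_model(),
                                pixel_size = 3) {
  if (any(mu_slice < 0)) stop("attenuation coefficients must be nonnegative")
  exp(-0.1 * forward_project(mu_slice, model, pixel_size))
}

#' Simulate the counts of one time frame
#'
#' Expected counts per bin are the attenuated forward projection of the
#' activity scaled by `counts_scale`, the frame duration and the
#' frame-averaged radioactive decay factor; Poisson noise is sampled per bin
#' when `noise = TRUE`.
#'
#' @param activity 3D activity volume (kBq/mL) for the frame, or a single
#'   slice matrix.
#' @param truth_mu matching attenuation volume/slice (cm^-1).
#' @param frame frame index into `schedule`.
#' @param schedule a [frame_schedule()].
#' @param model an [acquisition_model()].
#' @param seed integer seed for the Poisson draw.
#' @param pixel_size mm.
#' @param noise Poisson sampling on/off.
#' @param slices integer vector of slice indices to simulate (default all).
#' @return counts array (`n_bins` x `n_angles` x `n_slices`).
#' @export
simulate_frame <- function(activity, truth_mu, frame, schedule, model,
                           seed = 1L, pixel_size = 3, noise = TRUE,
                           slices = NULL) {
  if (any(activity < 0)) stop("activity must be nonnegative")
  act <- if (length(dim(activity)) == 2) {
    array(activity, c(dim(activity), 1))
  } else activity
  mu <- if (length(dim(truth_mu)) == 2) {
    array(truth_mu, c(dim(truth_mu), 1))
  } else as_mu_volume(truth_mu)
  if (is.null(slices)) slices <- seq_len(dim(act)[3])
  g <- resolve_geometry(model, dim(act)[1], pixel_size)
  dec <- decay_factors(schedule, model$half_life)[frame]
  scale <- model$counts_scale * schedule$duration[frame] * dec
  out <- array(0, c(g$nbins, g$nang, dim(act)[3]))
  with_seed(seed, {
    for (z in slices) {
      proj <- cpp_forward_project(act[, , z], g$nang, g$nbins, g$bw, g$p,
                                  g$step)
      acf <- exp(-0.1 * cpp_forward_project(mu[, , z], g$nang, g$nbins, g$bw,
                                            g$p, g$step))
      expected <- scale * acf * proj
      out[, , z] <- if (noise) {
        array(rpois(length(expected), expected), dim(expected))
      } else expected
    }
  })
  out
}

#' Reconstruct one frame with a candidate attenuation map
#'
#' OSEM (MLEM for `n_subsets = 1`) with the candidate map's attenuation
#' factors inside the system model. The counts-to-activity scaling inverts
#' the simulation scaling, so with a matched map and noise-free data the
#' reconstruction converges to the frame-averaged decayed activity;
#' `decay_correct` then restores injection-time activity.
#'
#' @param counts counts array from [simulate_frame()].
#' @param candidate_mu attenuation volume/slice used for correction.
#' @inheritParams simulate_frame
#' @param n_iterations OSEM iterations.
#' @param n_subsets angle subsets per iteration.
#' @return reconstructed activity volume (kBq/mL), nonnegative.
#' @export
reconstruct_frame <- function(counts, candidate_mu, frame, schedule, model,
                              pixel_size = 3, n_iterations = 20,
                              n_subsets = 16, slices = NULL) {
  mu <- if (length(dim(candidate_mu)) == 2) {
    array(candidate_mu, c(dim(candidate_mu), 1))
  } else as_mu_volume(candidate_mu)
  n <- dim(mu)[1]
  if (dim(counts)[3] != dim(mu)[3]) stop("counts and mu grids do not match")
  g <- resolve_geometry(model, n, pixel_size)
  if (dim(counts)[1] != g$nbins || dim(counts)[2] != g$nang) {
    stop("counts sinogram does not match the acquisition geometry")
  }
  if (is.null(slices)) slices <- seq_len(dim(mu)[3])
  dec <- decay_factors(schedule, model$half_life)[frame]
  # scale excludes decay: the raw reconstruction is frame-averaged decayed
  # activity, restored to injection time below when decay_correct is set
  scale <- model$counts_scale * schedule$duration[frame]
  out <- array(0, c(n, n, dim(mu)[3]))
  for (z in slices) {
    if (all(counts[, , z] == 0)) next
    acf <- exp(-0.1 * cpp_forward_project(mu[, , z], g$nang, g$nbins, g$bw,
                                          g$p, g$step))
    img <- cpp_osem(counts[, , z], acf, scale, n, g$bw, g$p, g$step,
                    as.integer(n_iterations), as.integer(n_subsets))
    out[, , z] <- img
  }
  if (model$decay_correct) out <- out / dec
  out
}

#' Simulate a dynamic study and reconstruct it with each candidate map
#'
#' One acquisition — a single Poisson realization per frame generated with
#' the true attenuation — is reconstructed once per candidate attenuation
#' map, so all candidates see identical counts and differ only in the
#' correction, mirroring the study design.
#'
#' @param true_dynamic a [dynamic_image()] of ground-truth activity.
#' @param truth_mu true attenuation map used for the acquisition.
#' @param candidate_mu_list named list of [mu_map()]s used for
#'   reconstruction.
#' @inheritParams simulate_frame
#' @inheritParams reconstruct_frame
#' @return named list of [dynamic_image()]s, one per candidate.
#' @export
simulate_dynamic_study <- function(true_dynamic, truth_mu, candidate_mu_list,
                                   model = acquisition_model(), seed = 1L,
                                   pixel_size = 3, noise = TRUE,
                                   n_iterations = 20, n_subsets = 16,
                                   slices = NULL) {
  if (length(candidate_mu_list) == 0) stop("candidate map list is empty")
  sch <- true_dynamic$schedule
  nf <- nframes(sch)
  dm <- dim(true_dynamic$data)[1:3]
  for (cand in candidate_mu_list) {
    if (!all(dim(as_mu_volume(cand)) == dm)) {
      stop("candidate maps must share the activity grid")
    }
  }
  if (is.null(slices)) slices <- seq_len(dm[3])
  out <- lapply(candidate_mu_list, function(cand) {
    array(0, c(dm, nf))
  })
  for (f in seq_len(nf)) {
    counts <- simulate_frame(
      true_dynamic$data[, , , f], truth_mu, f, sch, model,
      seed = derive_seed(seed, f), pixel_size = pixel_size, noise = noise,
      slices = slices
    )
    for (m in seq_along(candidate_mu_list)) {
      out[[m]][, , , f] <- reconstruct_frame(
        counts, candidate_mu_list[[m]], f, sch, model, pixel_size,
        n_iterations, n_subsets, slices = slices
      )
    }
  }
  tags <- names(candidate_mu_list)
  if (is.null(tags)) tags <- paste0("method", seq_along(candidate_mu_list))
  res <- lapply(seq_along(out), function(m) {
    dynamic_image(out[[m]], sch, subject_id = true_dynamic$subject_id,
                  ac_method = tags[m])
  })
  names(res) <- tags
  res
}
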