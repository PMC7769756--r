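#' Experiment configuration
#'
#' Collects every tunable of the end-to-end comparison in one object. Each
#' stochastic stage derives its seed deterministically from the master seed
#' and the subject index, so a fixed configuration reproduces bit-identical
#' results. The default follows the study design: 9 subjects, 4
#' attenuation-correction methods with the transmission-like map as
#' reference, and the 22-frame 80-min schedule.
#'
#' @param master_seed integer master seed.
#' @param n_subjects number of simulated subjects.
#' @param grid_shape phantom grid (voxels per axis).
#' @param voxel_size mm per axis.
#' @param n_atlases atlas database size per subject.
#' @param deform_amplitude atlas deformation amplitude (mm).
#' @param methods candidate attenuation maps to reconstruct with.
#' @param reference method used as the comparison reference.
#' @param schedule a [frame_schedule()].
#' @param model an [acquisition_model()].
#' @param noise Poisson counting noise on/off.
#' @param n_iterations,n_subsets OSEM settings.
#' @param dose_per_kg injected dose per body weight (MBq/kg).
#' @param kinetic_table regional ground-truth parameters.
#' @param geometry phantom geometry from [phantom_geometry()].
#' @param out_dir optional output directory for NIfTI/TAC/report files.
#' @export
experiment_config <- function(master_seed = 1L, n_subjects = 9L,
                              grid_shape = c(64, 64, 64),
                              voxel_size = c(3, 3, 3),
                              n_atlases = 10L, deform_amplitude = 4,
                              methods = c("GE_REF", "ATLAS1", "MAXPROB", "ZTE"),
                              reference = "GE_REF",
                              schedule = default_frame_schedule(),
                              model = acquisition_model(),
                              noise = TRUE,
                              n_iterations = 20, n_subsets = 16,
                              dose_per_kg = 5,
                              kinetic_table = default_kinetic_table(),
                              geometry = phantom_geometry(),
                              out_dir = NULL) {
  if (!reference %in% methods) {
    stop("the reference method must be among the reconstructed methods")
  }
  structure(
    list(master_seed = as.integer(master_seed),
         n_subjects = as.integer(n_subjects),
         grid_shape = grid_shape, voxel_size = voxel_size,
         n_atlases = as.integer(n_atlases),
         deform_amplitude = deform_amplitude,
         methods = methods, reference = reference,
         schedule = schedule, model = model, noise = noise,
         n_iterations = n_iterations, n_subsets = n_subsets,
         dose_per_kg = dose_per_kg, kinetic_table = kinetic_table,
         geometry = geometry, out_dir = out_dir),
    class = "experiment_config"
  )
}

#' Build every candidate attenuation map for one subject
#'
#' @param ph a [make_phantom()] result.
#' @param config an [experiment_config()].
#' @param subject subject index (drives the derived seeds).
#' @return named list of [mu_map()]s (plus the atlas database as an
#'   attribute).
#' @export
subject_mu_maps <- function(ph, config, subject = 1L) {
  truth <- mu_map(ph$truth_mu, "TRUTH")
  head_mask <- ph$label_volume != LABEL_BG_AIR
  maps <- list()
  need_atlas <- any(c("ATLAS1", "MAXPROB") %in% config$methods)
  db <- NULL
  if (need_atlas) {
    db <- make_atlas_database(
      ph, n_atlases = config$n_atlases,
      deform_amplitude = config$deform_amplitude,
      seed = derive_seed(config$master_seed, subject, 2L)
    )
  }
  for (m in config$methods) {
    maps[[m]] <- switch(
      m,
      GE_REF = degrade_to_reference(
        truth, seed = derive_seed(config$master_seed, subject, 3L),
        voxel_size = config$voxel_size
      ),
      MAXPROB = {
        pct <- maxprob_pseudo_ct(ph$mr_volume, db, "oracle")
        hu_to_mu_bilinear(pct, method_tag = "MAXPROB")
      },
      ATLAS1 = {
        pct <- maxprob_pseudo_ct(ph$mr_volume, db[1], "oracle")
        hu_to_mu_bilinear(pct, method_tag = "ATLAS1")
      },
      ZTE = zte_like_segment(ph$zte_volume, head_mask),
      TRUTH = truth,
      stop(sprintf("unknown method '%s'", m))
    )
  }
  attr(maps, "atlas_db") <- db
  maps
}

# Mean parametric value over each labelled region; returns a long data.frame.
regional_parameter_values <- function(maps, region_map, subject, method) {
  rl <- region_labels()
  rows <- list()
  for (nm in setdiff(names(rl), "none")) {
    sel <- region_map == rl[[nm]]
    if (!any(sel)) next
    for (par in names(maps)) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject, method = method, region = nm, parameter = par,
        value = mean(maps[[par]][sel]), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# R1 cluster rows (anterior/posterior cortical, limbic, whole brain) from a
# parametric map; striatum is added later as a volume-weighted composite.
cluster_parameter_values <- function(maps, region_map, subject, method) {
  rl <- region_labels()
  grey <- setdiff(names(rl), c("none", "white-matter"))
  clusters <- list(
    ACR = "anterior-cortex", PCR = "posterior-cortex", LR = "limbic",
    WB = grey
  )
  rows <- list()
  for (cl in names(clusters)) {
    sel <- region_map %in% rl[clusters[[cl]]]
    dim(sel) <- dim(region_map)
    if (!any(sel)) next
    for (par in names(maps)) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject, method = method, region = cl, parameter = par,
        value = mean(maps[[par]][sel]), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Run the full synthetic comparison experiment
#'
#' For each subject: generate a phantom and its kinetic ground truth, build
#' all candidate attenuation maps, simulate one dynamic acquisition with the
#' true attenuation, reconstruct it once per candidate map, fit parametric
#' maps of relative delivery (R1) and binding potential (BP_ND) with the
#' cerebellar reference region, and extract regional values. Across
#' subjects, the accuracy/precision/agreement report and the SUV bias-curve
#' set are assembled against the reference method.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-stage progress.
#' @return list with `report` (a [build_report()] table), `values` (long
#'   per-subject regional values), `tac_curves` (per region x method
#'   [tac_bias_curves()]), `mu_bias` (per method mean attenuation bias in
#'   soft tissue and bone), and `config`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  values <- list()
  mu_bias <- list()
  dynamics_by_method <- stats::setNames(
    replicate(length(config$methods), list(), simplify = FALSE),
    config$methods
  )
  rl <- region_labels()
  region_map <- NULL
  striatal_volumes <- NULL

  for (s in seq_len(config$n_subjects)) {
    say("subject %d/%d: phantom", s, config$n_subjects)
    ph <- make_phantom(config$grid_shape, config$geometry,
                       seed = derive_seed(config$master_seed, s, 1L),
                       voxel_size = config$voxel_size)
    region_map <- ph$region_map
    truth <- assign_kinetics(ph$region_map, config$kinetic_table)
    say("subject %d: attenuation maps", s)
    maps <- subject_mu_maps(ph, config, s)

    # attenuation-map bias against the reference map (Eq. 1 analogue)
    head_mask <- ph$label_volume != LABEL_BG_AIR
    bone_m <- bone_mask_from_zte(
      if ("ZTE" %in% names(maps)) maps$ZTE else
        zte_like_segment(ph$zte_volume, head_mask)
    )
    soft_m <- soft_mask(maps[[config$reference]], roi = head_mask)
    for (m in setdiff(names(maps), config$reference)) {
      bm <- bias_map(maps[[m]], maps[[config$reference]], head_mask,
                     summary_masks = list(soft = soft_m, bone = bone_m))
      mu_bias[[length(mu_bias) + 1]] <- data.frame(
        subject = s, method = m,
        soft_bias = bm$summary[["soft"]], bone_bias = bm$summary[["bone"]],
        stringsAsFactors = FALSE
      )
    }

    say("subject %d: dynamic simulation", s)
    true_dyn <- true_dynamic_from_truth(ph, truth, config$schedule)
    true_dyn$subject_id <- sprintf("sub-%02d", s)
    head_slices <- which(apply(head_mask, 3, any))
    recons <- simulate_dynamic_study(
      true_dyn, ph$truth_mu, maps, model = config$model,
      seed = derive_seed(config$master_seed, s, 4L),
      pixel_size = config$voxel_size[1], noise = config$noise,
      n_iterations = config$n_iterations, n_subsets = config$n_subsets,
      slices = head_slices
    )

    say("subject %d: kinetic fits", s)
    brain_mask <- ph$label_volume == LABEL_SOFT
    ref_voi <- ph$region_map == rl[["cerebellum-GM"]]
    for (m in names(recons)) {
      fit <- fit_parametric_maps(recons[[m]], ref_voi, brain_mask)
      pmaps <- list(BP_ND = fit$BP_ND, R1 = fit$R1)
      values[[length(values) + 1]] <- rbind(
        regional_parameter_values(pmaps, ph$region_map, s, m),
        cluster_parameter_values(pmaps, ph$region_map, s, m)
      )
      dynamics_by_method[[m]][[s]] <- recons[[m]]
    }
    striatal_volumes <- c(
      caudate = sum(ph$region_map == rl[["caudate"]]),
      putamen = sum(ph$region_map == rl[["putamen"]])
    )

    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      sd <- file.path(config$out_dir, sprintf("sub-%02d", s))
      dir.create(sd, showWarnings = FALSE)
      write_volume(ph$truth_mu, file.path(sd, "mu_truth.nii.gz"),
                   config$voxel_size)
      for (m in names(maps)) {
        write_volume(maps[[m]]$mu_volume,
                     file.path(sd, sprintf("mu_%s.nii.gz", tolower(m))),
                     config$voxel_size)
      }
    }
  }

  values <- do.call(rbind, values)
  values <- add_weighted_region(values, "striatum",
                                c("caudate", "putamen"), striatal_volumes)
  values <- add_weighted_region(values, "STR",
                                c("caudate", "putamen"), striatal_volumes)
  say("report")
  report <- build_report(values, reference = config$reference)

  tac_curves <- list()
  curve_regions <- c("caudate", "putamen", "cerebellum-GM")
  for (reg in curve_regions) {
    voi <- region_map == rl[[reg]]
    for (m in setdiff(config$methods, config$reference)) {
      tac_curves[[paste(reg, m, sep = ".")]] <- tac_bias_curves(
        dynamics_by_method[[m]], dynamics_by_method[[config$reference]],
        voi, dose_per_kg = config$dose_per_kg, region = reg, method = m
      )
    }
  }

  mu_bias <- do.call(rbind, mu_bias)

  if (!is.null(config$out_dir)) {
    write.table(values, file.path(config$out_dir, "regional_values.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(as.data.frame(report),
                file.path(config$out_dir, "bias_report.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    cfg <- config
    cfg$schedule <- list(durations_s = config$schedule$duration)
    cfg$model <- unclass(config$model)
    cfg$kinetic_table <- NULL
    yaml::write_yaml(
      lapply(cfg[c("master_seed", "n_subjects", "grid_shape", "voxel_size",
                   "n_atlases", "deform_amplitude", "methods", "reference",
                   "noise", "n_iterations", "n_subsets", "dose_per_kg")],
             identity),
      file.path(config$out_dir, "config.yaml")
    )
  }

  list(report = report, values = values, tac_curves = tac_curves,
       mu_bias = mu_bias, config = config)
}
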