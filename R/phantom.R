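#' Geometry and intensity parameters for the digital head phantom
#'
#' The phantom is a concentric ellipsoidal construction: a closed bone shell
#' (skull) around interior soft tissue (brain), with two frontal sinus air
#' pockets and ellipsoidal anatomical regions (caudate, putamen, cerebellar
#' grey matter, anterior/posterior cortical bands, a limbic cluster and
#' central white matter). Sizes are expressed as fractions of the half-extent
#' of the grid so the same geometry scales across grid sizes.
#'
#' CT numbers are drawn per tissue class from truncated normals that respect
#' the segmentation thresholds used downstream: soft tissue N(30, 20) HU on
#' \[-500, 300\], bone N(900, 150) HU above 300 HU, air fixed at -1000 HU.
#' The proton-density-like (ZTE) intensity of bone decreases linearly with CT
#' HU so that a two-anchor intensity-to-HU calibration line can represent the
#' underlying relationship exactly; soft tissue forms the main histogram peak
#' at 1.0 (arbitrary units) and air sits near zero.
#'
#' @param shell_frac outer skull semi-axes as fractions of half-extent.
#' @param shell_thickness_mm skull thickness in mm.
#' @param sinus_radius_frac radius of each frontal sinus pocket.
#' @param ct_soft_mean,ct_soft_sd,ct_bone_mean,ct_bone_sd CT class
#'   distributions (HU).
#' @param mr_noise_sd,zte_noise_sd intensity noise (arbitrary units); set
#'   `zte_noise_sd = 0` for an ideal noise-free phantom.
#' @param zte_bone_intercept,zte_bone_slope bone ZTE intensity model:
#'   `zte = intercept + slope * HU` (normalized units per HU).
#' @return a list of geometry parameters consumed by [make_phantom()].
#' @export
phantom_geometry <- function(shell_frac = c(0.84, 0.90, 0.80),
                             shell_thickness_mm = 8,
                             sinus_radius_frac = 0.09,
                             ct_soft_mean = 30, ct_soft_sd = 20,
                             ct_bone_mean = 900, ct_bone_sd = 150,
                             mr_noise_sd = 0.04,
                             zte_noise_sd = 0.02,
                             zte_bone_intercept = 0.55,
                             zte_bone_slope = -1e-4) {
  list(
    shell_frac = shell_frac,
    shell_thickness_mm = shell_thickness_mm,
    sinus_radius_frac = sinus_radius_frac,
    ct_soft_mean = ct_soft_mean, ct_soft_sd = ct_soft_sd,
    ct_bone_mean = ct_bone_mean, ct_bone_sd = ct_bone_sd,
    mr_noise_sd = mr_noise_sd,
    zte_noise_sd = zte_noise_sd,
    zte_bone_intercept = zte_bone_intercept,
    zte_bone_slope = zte_bone_slope
  )
}

# Tissue class codes of the label volume.
LABEL_BG_AIR <- 0L
LABEL_SOFT <- 1L
LABEL_BONE <- 2L
LABEL_SINUS_AIR <- 3L

#' @rdname make_phantom
#' @export
region_labels <- function() {
  c(
    "none" = 0L, "caudate" = 1L, "putamen" = 2L, "cerebellum-GM" = 3L,
    "anterior-cortex" = 4L, "posterior-cortex" = 5L, "limbic" = 6L,
    "white-matter" = 7L
  )
}

#' Generate a digital head phantom
#'
#' Builds the seeded synthetic head used throughout the pipeline: tissue
#' labels, a CT volume in Hounsfield units, T1-like and proton-density-like
#' (ZTE) intensity volumes, an anatomical region map, and the ground-truth
#' 511 keV attenuation map obtained by bilinear HU conversion of the CT.
#'
#' The bone label forms a closed shell: a 6-connected flood fill from the
#' volume border through non-bone voxels cannot reach any labelled anatomical
#' region. This is verified at construction time and an error is raised for
#' geometries that cannot produce a closed shell.
#'
#' @param grid_shape integer vector of voxel counts per axis (each >= 32).
#' @param geometry parameter list from [phantom_geometry()].
#' @param seed integer seed; results are bit-identical for a fixed seed.
#' @param voxel_size voxel edge lengths in mm.
#' @return an object of class `phantom` with fields `label_volume`,
#'   `ct_volume`, `mr_volume`, `zte_volume`, `region_map`, `truth_mu`,
#'   `voxel_size`.
#' @export
make_phantom <- function(grid_shape = c(64, 64, 64),
                         geometry = phantom_geometry(),
                         seed = 1L,
                         voxel_size = c(3, 3, 3)) {
  grid_shape <- as.integer(rep(grid_shape, length.out = 3))
  voxel_size <- rep(voxel_size, length.out = 3)
  if (any(grid_shape < 32L)) stop("grid_shape must be >= 32 per axis")
  h <- min(grid_shape * voxel_size) / 2
  outer_semi <- geometry$shell_frac * (grid_shape * voxel_size) / 2
  inner_semi <- outer_semi - geometry$shell_thickness_mm
  if (any(inner_semi <= 4 * max(voxel_size))) {
    stop("invalid geometry: shell does not fit inside the grid")
  }

  g <- coord_grids(grid_shape, voxel_size)
  outer <- ellipsoid_mask(g, c(0, 0, 0), outer_semi)
  inner <- ellipsoid_mask(g, c(0, 0, 0), inner_semi)
  label <- array(LABEL_BG_AIR, grid_shape)
  label[outer & !inner] <- LABEL_BONE
  label[inner] <- LABEL_SOFT

  # frontal sinus air pockets, fully inside the soft-tissue compartment
  sr <- geometry$sinus_radius_frac * h
  for (sx in c(-0.18, 0.18)) {
    sin_m <- ellipsoid_mask(
      g, c(sx * h, 0.55 * inner_semi[2], -0.25 * h), rep(sr, 3)
    )
    label[sin_m & inner] <- LABEL_SINUS_AIR
  }

  # anatomical regions (assigned only on soft tissue)
  rl <- region_labels()
  region <- array(rl[["none"]], grid_shape)
  soft <- label == LABEL_SOFT
  assign_region <- function(mask, name) {
    region[mask & soft] <<- rl[[name]]
  }
  core <- ellipsoid_mask(g, c(0, 0.05 * h, 0.05 * h),
                         c(0.45, 0.50, 0.40) * h)
  assign_region(core, "white-matter")
  cortex_band <- ellipsoid_mask(g, c(0, 0, 0), inner_semi * 0.97) & !core
  assign_region(cortex_band & g$y > 0.30 * h & g$z > -0.15 * h,
                "anterior-cortex")
  assign_region(cortex_band & g$y < -0.28 * h & g$z > 0.05 * h,
                "posterior-cortex")
  assign_region(ellipsoid_mask(g, c(0, -0.10 * h, -0.05 * h),
                               c(0.16, 0.12, 0.10) * h), "limbic")
  assign_region(ellipsoid_mask(g, c(0, -0.42 * h, -0.38 * h),
                               c(0.34, 0.22, 0.16) * h), "cerebellum-GM")
  for (sx in c(-1, 1)) {
    assign_region(ellipsoid_mask(g, c(sx * 0.16 * h, 0.14 * h, 0.10 * h),
                                 c(0.07, 0.12, 0.09) * h), "caudate")
    assign_region(ellipsoid_mask(g, c(sx * 0.30 * h, 0.02 * h, 0.05 * h),
                                 c(0.08, 0.13, 0.10) * h), "putamen")
  }

  # shell closure: border flood fill through non-bone must not reach regions
  reach <- flood_fill_border(label != LABEL_BONE)
  if (any(reach & region != rl[["none"]])) {
    stop("invalid geometry: bone shell is not closed around labelled regions")
  }

  ph <- with_seed(seed, {
    ct <- array(-1000, grid_shape)
    n_soft <- sum(soft)
    n_bone <- sum(label == LABEL_BONE)
    ct[soft] <- rnorm_trunc(n_soft, geometry$ct_soft_mean, geometry$ct_soft_sd,
                            lower = -500, upper = 300)
    ct[label == LABEL_BONE] <- rnorm_trunc(
      n_bone, geometry$ct_bone_mean, geometry$ct_bone_sd,
      lower = 300 + 1e-6, upper = 3000
    )

    mr <- array(0, grid_shape)
    mr[soft] <- 1.0
    mr[region == rl[["white-matter"]]] <- 1.15
    mr[label == LABEL_BONE] <- 0.25
    mr <- mr + rnorm(length(mr), 0, geometry$mr_noise_sd)
    mr <- pmax(mr, 0)

    zte <- array(0.02, grid_shape)
    zte[soft] <- 1.0
    bone_idx <- which(label == LABEL_BONE)
    zte[bone_idx] <- geometry$zte_bone_intercept +
      geometry$zte_bone_slope * ct[bone_idx]
    if (geometry$zte_noise_sd > 0) {
      zte <- zte + rnorm(length(zte), 0, geometry$zte_noise_sd)
    }
    zte <- pmax(zte, 0)
    list(ct = ct, mr = mr, zte = zte)
  })

  structure(
    list(
      label_volume = label,
      ct_volume = ph$ct,
      mr_volume = ph$mr,
      zte_volume = ph$zte,
      region_map = region,
      truth_mu = hu_to_mu_bilinear(ph$ct)$mu_volume,
      voxel_size = voxel_size,
      geometry = geometry,
      seed = as.integer(seed)
    ),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  dm <- dim(x$label_volume)
  cat(sprintf(
    "<phantom> %dx%dx%d voxels (%.1f mm), %d bone / %d soft voxels\n",
    dm[1], dm[2], dm[3], x$voxel_size[1],
    sum(x$label_volume == LABEL_BONE), sum(x$label_volume == LABEL_SOFT)
  ))
  invisible(x)
}

# --- atlas database ---------------------------------------------------------

# Smooth random displacement field in voxel units: iid normal displacements on
# a coarse control grid, trilinearly upsampled. Returns array c(shape, 3).
random_displacement <- function(shape, amplitude_vox, n_control = 5L) {
  if (amplitude_vox <= 0) return(array(0, c(shape, 3)))
  u <- array(0, c(shape, 3))
  for (d in 1:3) {
    ctrl <- array(rnorm(n_control^3, 0, amplitude_vox), rep(n_control, 3))
    u[, , , d] <- upsample3(ctrl, shape)
  }
  u
}

# Trilinear upsampling of a coarse 3D array onto `shape`.
upsample3 <- function(coarse, shape) {
  nc <- dim(coarse)
  # coordinates of fine voxels in coarse index space (1..nc)
  ax <- lapply(1:3, function(d) {
    seq(1, nc[d], length.out = shape[d])
  })
  sample_trilinear(
    coarse,
    array(rep(ax[[1]], times = shape[2] * shape[3]), dim = shape),
    array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), dim = shape),
    array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape)
  )
}

# Trilinear sampling of a 3D array at (possibly fractional) 1-based index
# coordinates; out-of-volume samples clamp to the border value.
sample_trilinear <- function(vol, xi, yi, zi) {
  dm <- dim(vol)
  out_dim <- dim(xi)
  xi <- pmin(pmax(as.vector(xi), 1), dm[1])
  yi <- pmin(pmax(as.vector(yi), 1), dm[2])
  zi <- pmin(pmax(as.vector(zi), 1), dm[3])
  x0 <- pmin(floor(xi), dm[1] - 1); y0 <- pmin(floor(yi), dm[2] - 1)
  z0 <- pmin(floor(zi), dm[3] - 1)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  idx <- function(a, b, c) a + dm[1] * (b - 1 + dm[2] * (c - 1))
  v <- vol[idx(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    vol[idx(x0 + 1, y0, z0)] * fx * (1 - fy) * (1 - fz) +
    vol[idx(x0, y0 + 1, z0)] * (1 - fx) * fy * (1 - fz) +
    vol[idx(x0 + 1, y0 + 1, z0)] * fx * fy * (1 - fz) +
    vol[idx(x0, y0, z0 + 1)] * (1 - fx) * (1 - fy) * fz +
    vol[idx(x0 + 1, y0, z0 + 1)] * fx * (1 - fy) * fz +
    vol[idx(x0, y0 + 1, z0 + 1)] * (1 - fx) * fy * fz +
    vol[idx(x0 + 1, y0 + 1, z0 + 1)] * fx * fy * fz
  if (!is.null(out_dim)) array(v, out_dim) else v
}

#' Apply a displacement field to a volume
#'
#' The warped volume samples the input at `x + u(x)` (voxel units) with
#' trilinear interpolation, the standard backward-warping convention.
#'
#' @param vol 3D array.
#' @param disp displacement field, array of dim `c(dim(vol), 3)` in voxels.
#' @return warped 3D array of the same shape.
#' @export
apply_displacement <- function(vol, disp) {
  dm <- dim(vol)
  base <- coord_index_grids(dm)
  out <- sample_trilinear(
    vol,
    base$x + disp[, , , 1],
    base$y + disp[, , , 2],
    base$z + disp[, , , 3]
  )
  array(out, dm)
}

coord_index_grids <- function(dm) {
  list(
    x = array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dim = dm),
    y = array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dim = dm),
    z = array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dim = dm)
  )
}

# Fixed-point inversion of a displacement field: find v with
# v(x) = -u(x + v(x)), so that warping by u then by v is identity.
invert_displacement <- function(disp, n_iter = 15L) {
  dm <- dim(disp)[1:3]
  v <- -disp
  base <- coord_index_grids(dm)
  for (it in seq_len(n_iter)) {
    for (d in 1:3) {
      v[, , , d] <- -sample_trilinear(
        disp[, , , d],
        base$x + v[, , , 1], base$y + v[, , , 2], base$z + v[, , , 3]
      )
    }
  }
  v
}

# Max |negative part| of det(I + grad u) via central differences; used to
# reject folding deformations.
min_jacobian <- function(disp) {
  dm <- dim(disp)[1:3]
  grad <- array(0, c(dm, 3, 3))
  for (d in 1:3) {
    for (e in 1:3) {
      u <- disp[, , , d]
      up <- u; dn <- u
      idx <- seq_len(dm[e])
      if (e == 1) {
        up[head(idx, -1), , ] <- u[tail(idx, -1), , ]
        dn[tail(idx, -1), , ] <- u[head(idx, -1), , ]
      } else if (e == 2) {
        up[, head(idx, -1), ] <- u[, tail(idx, -1), ]
        dn[, tail(idx, -1), ] <- u[, head(idx, -1), ]
      } else {
        up[, , head(idx, -1)] <- u[, , tail(idx, -1)]
        dn[, , tail(idx, -1)] <- u[, , head(idx, -1)]
      }
      grad[, , , d, e] <- (up - dn) / 2
    }
  }
  a <- function(d, e) grad[, , , d, e] + (d == e)
  det <- a(1, 1) * (a(2, 2) * a(3, 3) - a(2, 3) * a(3, 2)) -
    a(1, 2) * (a(2, 1) * a(3, 3) - a(2, 3) * a(3, 1)) +
    a(1, 3) * (a(2, 1) * a(3, 2) - a(2, 2) * a(3, 1))
  min(det)
}

#' Build a database of deformed MR/CT atlas pairs
#'
#' Each atlas is the template phantom warped by a random smooth invertible
#' displacement field (iid normal control-point displacements, trilinearly
#' upsampled) plus class-preserving intensity jitter on the MR channel. The
#' true forward and inverse transforms are stored with each pair, which lets
#' the multi-atlas voting stage run in oracle-registration mode.
#'
#' @param template a [make_phantom()] result.
#' @param n_atlases number of MR/CT pairs (the study-scale database is 40).
#' @param deform_amplitude displacement amplitude in mm (0 gives identity).
#' @param seed integer seed.
#' @param n_control control points per axis of the deformation grid.
#' @return list of `atlas_pair` objects with fields `mr`, `ct`, `transform`
#'   (`disp`, `inv_disp`, voxel units) and `id`.
#' @export
make_atlas_database <- function(template, n_atlases = 10L,
                                deform_amplitude = 4, seed = 1L,
                                n_control = 5L) {
  stopifnot(inherits(template, "phantom"))
  if (n_atlases < 1L) stop("n_atlases must be >= 1")
  if (deform_amplitude < 0) stop("deform_amplitude must be >= 0")
  dm <- dim(template$ct_volume)
  amp_vox <- deform_amplitude / mean(template$voxel_size)
  with_seed(seed, {
    lapply(seq_len(n_atlases), function(i) {
      disp <- random_displacement(dm, amp_vox, n_control)
      if (min_jacobian(disp) < 0.05) {
        stop(sprintf(
          "deformation for atlas %d folds space; reduce deform_amplitude", i
        ))
      }
      ct <- apply_displacement(template$ct_volume, disp)
      mr <- apply_displacement(template$mr_volume, disp)
      # class-preserving MR intensity jitter (global gain + additive noise)
      gain <- rnorm(1, 1, 0.03)
      mr <- pmax(mr * gain + rnorm(length(mr), 0, 0.02), 0)
      inv <- if (deform_amplitude > 0) invert_displacement(disp) else disp
      structure(
        list(
          mr = array(mr, dm), ct = ct,
          transform = list(disp = disp, inv_disp = inv),
          id = sprintf("atlas-%02d", i)
        ),
        class = "atlas_pair"
      )
    })
  })
}

# --- kinetic ground truth ---------------------------------------------------

#' Regional kinetic parameter table used as simulation ground truth
#'
#' Default SRTM parameters per anatomical region. Striatal regions (caudate,
#' putamen) carry high non-displaceable binding potential as expected for a
#' dopamine-transporter ligand; cerebellar grey matter is the reference region
#' with R1 = 1 and BP_ND = 0 (k2a = k2).
#'
#' @return data.frame with columns `region`, `R1`, `k2`, `k2a` (min^-1).
#' @export
default_kinetic_table <- function() {
  data.frame(
    region = c("caudate", "putamen", "cerebellum-GM", "anterior-cortex",
               "posterior-cortex", "limbic", "white-matter"),
    R1 = c(0.95, 0.95, 1.00, 1.05, 1.00, 0.90, 0.60),
    k2 = c(0.35, 0.35, 0.35, 0.40, 0.38, 0.32, 0.20),
    k2a = c(0.35 / 5.0, 0.35 / 5.4, 0.35, 0.40 / 1.3, 0.38 / 1.25,
            0.32 / 1.6, 0.20 / 1.2),
    stringsAsFactors = FALSE
  )
}

#' Attach kinetic ground truth to a phantom's region map
#'
#' Validates the parameter table against the regions present and computes
#' BP_ND = k2/k2a - 1 for each region. The cerebellar reference region must
#' have R1 = 1 and BP_ND = 0 exactly.
#'
#' @param region_map integer region volume (codes from [region_labels()]).
#' @param parameter_table data.frame with columns `region`, `R1`, `k2`, `k2a`.
#' @return object of class `kinetic_truth`: the table with a `BP_ND` column.
#' @export
assign_kinetics <- function(region_map, parameter_table = default_kinetic_table()) {
  rl <- region_labels()
  present <- names(rl)[rl %in% unique(as.vector(region_map))]
  present <- setdiff(present, "none")
  missing <- setdiff(present, parameter_table$region)
  if (length(missing) > 0) {
    stop(sprintf("parameter table is missing region(s): %s",
                 paste(missing, collapse = ", ")))
  }
  tab <- parameter_table
  if (any(!is.finite(tab$R1)) || any(tab$k2 <= 0) || any(tab$k2a <= 0)) {
    stop("all kinetic rates must be finite and > 0")
  }
  tab$BP_ND <- tab$k2 / tab$k2a - 1
  ref <- tab[tab$region == "cerebellum-GM", ]
  if (nrow(ref) == 1 && (abs(ref$BP_ND) > 1e-12 || abs(ref$R1 - 1) > 1e-12)) {
    stop("reference region cerebellum-GM must have R1 = 1 and BP_ND = 0")
  }
  structure(tab, class = c("kinetic_truth", "data.frame"))
}
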