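#' @useDynLib petmrac, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif sd median qnorm pnorm pchisq cor approx
#' @importFrom utils head tail write.table read.table
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derived from a master seed and a stage/subject index.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) {
    s <- (s * 69069 + as.double(k) * 104729 + 12345) %% 2147483647
  }
  as.integer(s)
}

# Truncated normal draws by rejection; bounds may be +-Inf.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0L) return(numeric(0))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
  }
  if (length(bad) > 0L) out[bad] <- pmin(pmax(out[bad], lower), upper)
  out
}

# Voxel-centre coordinate grids (mm, origin at volume centre) for a 3D shape.
coord_grids <- function(shape, voxel_size) {
  ax <- lapply(seq_len(3), function(d) {
    (seq_len(shape[d]) - (shape[d] + 1) / 2) * voxel_size[d]
  })
  list(
    x = array(rep(ax[[1]], times = shape[2] * shape[3]), dim = shape),
    y = array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), dim = shape),
    z = array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape)
  )
}

# Logical mask of an axis-aligned ellipsoid: centre (mm), semi-axes (mm).
ellipsoid_mask <- function(grids, centre, semi) {
  ((grids$x - centre[1]) / semi[1])^2 +
    ((grids$y - centre[2]) / semi[2])^2 +
    ((grids$z - centre[3]) / semi[3])^2 <= 1
}

# Separable Gaussian smoothing of a 3D array; fwhm in mm per axis,
# voxel_size mm. fwhm of 0 returns the input unchanged.
gaussian_smooth3 <- function(vol, fwhm, voxel_size) {
  if (all(fwhm <= 0)) return(vol)
  fwhm <- rep(fwhm, length.out = 3)
  voxel_size <- rep(voxel_size, length.out = 3)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size  # in voxels
  out <- vol
  for (d in 1:3) {
    if (sigma[d] <= 0) next
    r <- max(1L, ceiling(3 * sigma[d]))
    k <- exp(-0.5 * ((-r:r) / sigma[d])^2)
    k <- k / sum(k)
    out <- convolve_axis3(out, k, d)
  }
  out
}

# 1D convolution along axis d of a 3D array with replicate padding.
convolve_axis3 <- function(vol, kernel, d) {
  dm <- dim(vol)
  perm <- switch(d, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  v <- aperm(vol, perm)
  n <- dim(v)[1]
  m <- prod(dim(v)[2:3])
  mat <- matrix(v, nrow = n, ncol = m)
  r <- (length(kernel) - 1L) / 2L
  padded <- rbind(
    mat[rep(1L, r), , drop = FALSE],
    mat,
    mat[rep(n, r), , drop = FALSE]
  )
  out <- matrix(0, nrow = n, ncol = m)
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * padded[j:(j + n - 1L), , drop = FALSE]
  }
  res <- array(out, dim = dim(v))
  aperm(res, order(perm))
}

# 6-connected binary erosion, applied `times` times.
erode6 <- function(mask, times = 1L) {
  m <- mask
  dm <- dim(m)
  for (it in seq_len(times)) {
    if (!any(m)) break
    shifted <- function(dx, dy, dz) {
      out <- array(FALSE, dm)
      xs <- seq_len(dm[1]); ys <- seq_len(dm[2]); zs <- seq_len(dm[3])
      sx <- xs + dx; sy <- ys + dy; sz <- zs + dz
      okx <- sx >= 1 & sx <= dm[1]; oky <- sy >= 1 & sy <= dm[2]
      okz <- sz >= 1 & sz <= dm[3]
      out[xs[okx], ys[oky], zs[okz]] <- m[sx[okx], sy[oky], sz[okz]]
      out
    }
    m <- m & shifted(1, 0, 0) & shifted(-1, 0, 0) &
      shifted(0, 1, 0) & shifted(0, -1, 0) &
      shifted(0, 0, 1) & shifted(0, 0, -1)
  }
  m
}

# 6-connected flood fill over `open` voxels starting from all border voxels.
# Returns the reachable mask. Used to verify the bone shell is closed.
flood_fill_border <- function(open) {
  dm <- dim(open)
  seed <- array(FALSE, dm)
  seed[1, , ] <- TRUE; seed[dm[1], , ] <- TRUE
  seed[, 1, ] <- TRUE; seed[, dm[2], ] <- TRUE
  seed[, , 1] <- TRUE; seed[, , dm[3]] <- TRUE
  reach <- seed & open
  repeat {
    grown <- dilate6(reach) & open
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  reach
}

# 6-connected binary dilation (single step).
dilate6 <- function(mask) {
  dm <- dim(mask)
  out <- mask
  sh <- function(dx, dy, dz) {
    res <- array(FALSE, dm)
    xs <- seq_len(dm[1]); ys <- seq_len(dm[2]); zs <- seq_len(dm[3])
    sx <- xs + dx; sy <- ys + dy; sz <- zs + dz
    okx <- sx >= 1 & sx <= dm[1]; oky <- sy >= 1 & sy <= dm[2]
    okz <- sz >= 1 & sz <= dm[3]
    res[xs[okx], ys[oky], zs[okz]] <- mask[sx[okx], sy[oky], sz[okz]]
    res
  }
  out | sh(1, 0, 0) | sh(-1, 0, 0) | sh(0, 1, 0) | sh(0, -1, 0) |
    sh(0, 0, 1) | sh(0, 0, -1)
}
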