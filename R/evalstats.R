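#' Voxel-wise attenuation-map bias
#'
#' Difference map `candidate - reference` (cm^-1) within a mask, the
#' voxel-level comparison applied to every candidate attenuation map against
#' the transmission-like reference.
#'
#' @param candidate,reference [mu_map()]s or arrays on a shared grid.
#' @param mask logical array restricting the comparison (default: everywhere).
#' @param summary_masks optional named list of logical arrays (e.g. soft
#'   tissue and bone compartments) over which mean bias is reported.
#' @return list with `bias` (difference volume, 0 outside the mask), `mask`,
#'   `mean` (mean bias within the mask) and `summary` (named means).
#' @export
bias_map <- function(candidate, reference, mask = NULL, summary_masks = list()) {
  cand <- as_mu_volume(candidate)
  ref <- as_mu_volume(reference)
  if (!all(dim(cand) == dim(ref))) stop("bias_map requires a shared grid")
  if (is.null(mask)) mask <- array(TRUE, dim(cand))
  diff <- (cand - ref) * mask
  summaries <- vapply(summary_masks, function(m) {
    sel <- m & mask
    if (!any(sel)) return(NA_real_)
    mean(diff[sel])
  }, numeric(1))
  list(bias = diff, mask = mask,
       mean = if (any(mask)) mean(diff[mask]) else NA_real_,
       summary = summaries)
}

#' Bone and soft-tissue compartment masks
#'
#' The bone mask is a simple segmentation of the ZTE-derived attenuation map
#' (values above the fixed soft-tissue coefficient plus a margin) followed by
#' 6-connected binary erosion, by default applied twice ("2-pixel"), which
#' reduces the probability of the mask coinciding with other tissues.
#'
#' @param zte_mu a [mu_map()] from [zte_like_segment()] (or array).
#' @param erosion_px number of erosion passes (>= 0).
#' @param soft_tissue_mu,margin bone threshold is `soft_tissue_mu + margin`.
#' @return logical array.
#' @export
bone_mask_from_zte <- function(zte_mu, erosion_px = 2, soft_tissue_mu = 0.100,
                               margin = 0.005) {
  if (erosion_px < 0) stop("erosion_px must be >= 0")
  m <- as_mu_volume(zte_mu) > soft_tissue_mu + margin
  erode6(m, as.integer(erosion_px))
}

#' @rdname bone_mask_from_zte
#' @param reference_mu the reference attenuation map.
#' @param roi optional logical array to intersect (the "large VOI").
#' @param lower,upper soft-tissue attenuation window (cm^-1).
#' @export
soft_mask <- function(reference_mu, roi = NULL, lower = 0.085, upper = 0.105) {
  v <- as_mu_volume(reference_mu)
  m <- v >= lower & v <= upper
  if (!is.null(roi)) m <- m & roi
  m
}

#' Relative bias in percent
#'
#' `100 * (candidate - reference) / reference`, the accuracy measure applied
#' to outcome parameters and SUV values; its standard deviation across
#' subjects is the precision measure.
#'
#' @param candidate_value,reference_value numeric vectors (recycled).
#' @return percent bias, vectorized.
#' @export
relative_bias <- function(candidate_value, reference_value) {
  if (any(reference_value == 0)) {
    stop("relative bias is undefined for a zero reference value")
  }
  100 * (candidate_value - reference_value) / reference_value
}

#' Deming regression
#'
#' Errors-in-both-variables straight-line fit. `lambda` is the ratio of the
#' measurement-error variance of `y` to that of `x`; `lambda = 1` gives
#' orthogonal regression and `lambda -> Inf` recovers ordinary least squares
#' of `y` on `x`.
#'
#' @param x reference values; @param y candidate values.
#' @param lambda error-variance ratio (default 1).
#' @return list with `slope` and `intercept`.
#' @export
deming_regression <- function(x, y, lambda = 1) {
  if (length(x) < 3 || length(x) != length(y)) {
    stop("deming_regression needs n >= 3 paired values")
  }
  if (stats::var(x) == 0) stop("x must not be constant")
  mx <- mean(x); my <- mean(y)
  sxx <- mean((x - mx)^2)
  syy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sxy == 0) {
    slope <- 0
  } else {
    slope <- (syy - lambda * sxx +
                sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) / (2 * sxy)
  }
  list(slope = slope, intercept = my - slope * mx)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (the standard treatment of ties).
#'
#' @param x,y numeric vectors, length >= 3.
#' @return correlation coefficient in \[-1, 1\].
#' @export
spearman_r <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    stop("spearman_r needs n >= 3 paired values")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("spearman_r is undefined for constant input")
  }
  stats::cor(rank(x), rank(y))
}

#' Friedman test with Dunn-adjusted comparisons to a reference column
#'
#' Within-subject mid-ranks with tie correction: the statistic is
#' `(k - 1) * sum_j (R_j - n(k+1)/2)^2 / sum_ij (r_ij - (k+1)/2)^2`,
#' referred to a chi-squared distribution with `k - 1` degrees of freedom.
#' Post-hoc comparisons of each method against the reference use Dunn's z on
#' mean ranks with Bonferroni-style adjustment over the `k - 1` comparisons.
#'
#' For small designs (at most `exact_limit` within-subject rank
#' permutations) the p-value is exact, from full enumeration of the
#' permutation distribution of the statistic; larger designs use the
#' chi-squared approximation.
#'
#' @param values numeric matrix, subjects in rows, methods in columns
#'   (column names identify the methods).
#' @param reference_column name or index of the reference method.
#' @param exact_limit enumeration budget for the exact permutation p-value.
#' @return list with `statistic`, `friedman_p`, `mean_ranks` and
#'   `dunn_adjusted_p` (named per non-reference method).
#' @export
friedman_dunn <- function(values, reference_column = 1, exact_limit = 5000) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (k < 2) stop("friedman_dunn needs at least 2 methods")
  if (n < 2) stop("friedman_dunn needs at least 2 subjects")
  if (is.character(reference_column)) {
    reference_column <- match(reference_column, colnames(values))
    if (is.na(reference_column)) stop("reference column not found")
  }
  r <- t(apply(values, 1, rank))
  Rj <- colSums(r)
  stat_fun <- function(rmat) {
    centred <- rmat - (k + 1) / 2
    denom <- sum(centred^2)
    if (denom < 1e-12) return(0)
    (k - 1) * sum((colSums(rmat) - n * (k + 1) / 2)^2) / denom
  }
  stat <- stat_fun(r)
  n_perm <- factorial(k)^n
  if (stat == 0) {
    p <- 1
  } else if (n_perm <= exact_limit) {
    perms <- permutations_of(k)
    combos <- rep(list(seq_len(nrow(perms))), n)
    idx_grid <- as.matrix(expand.grid(combos))
    stats_all <- apply(idx_grid, 1, function(sel) {
      rp <- do.call(rbind, lapply(seq_len(n), function(i) r[i, perms[sel[i], ]]))
      stat_fun(rp)
    })
    p <- mean(stats_all >= stat - 1e-9)
  } else {
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  mean_ranks <- Rj / n
  others <- setdiff(seq_len(k), reference_column)
  se <- sqrt(k * (k + 1) / (6 * n))
  z <- (mean_ranks[others] - mean_ranks[reference_column]) / se
  dunn <- pmin(1, (k - 1) * 2 * stats::pnorm(-abs(z)))
  nm <- colnames(values)
  if (is.null(nm)) nm <- paste0("method", seq_len(k))
  names(dunn) <- nm[others]
  names(mean_ranks) <- nm
  list(statistic = stat, friedman_p = p, mean_ranks = mean_ranks,
       dunn_adjusted_p = dunn)
}

# All permutations of 1..k as rows (k is small: methods, not subjects).
permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    cbind(k, sub)[, append(seq_len(k - 1L) + 1L, 1L, after = pos - 1L),
                  drop = FALSE]
  }))
}

#' Bias of standardized uptake values over time
#'
#' Per frame, the relative bias of VOI-mean SUV of each candidate
#' reconstruction against the reference reconstruction is computed per
#' subject; mean and SD across subjects give the bias curve.
#'
#' @param candidate_dynamics list over subjects of [dynamic_image()]s for one
#'   method.
#' @param reference_dynamics matching list of reference reconstructions.
#' @param voi logical array defining the region.
#' @param dose_per_kg injected dose per body weight (MBq/kg).
#' @param region,method labels stored on the curve.
#' @return object of class `tac_bias_curve`: per-frame `mean` and `sd` (%).
#' @export
tac_bias_curves <- function(candidate_dynamics, reference_dynamics, voi,
                            dose_per_kg = 5, region = "", method = "") {
  if (length(candidate_dynamics) != length(reference_dynamics)) {
    stop("candidate and reference subject lists differ in length")
  }
  biases <- vapply(seq_along(candidate_dynamics), function(s) {
    cd <- candidate_dynamics[[s]]
    rd <- reference_dynamics[[s]]
    stopifnot_same_schedule(cd$schedule, rd$schedule)
    sc <- to_suv(extract_tac(cd, voi), dose_per_kg)$suv
    sr <- to_suv(extract_tac(rd, voi), dose_per_kg)$suv
    relative_bias(sc, sr)
  }, numeric(nframes(candidate_dynamics[[1]]$schedule)))
  biases <- matrix(biases, ncol = length(candidate_dynamics))
  structure(
    list(mean = rowMeans(biases),
         sd = apply(biases, 1, stats::sd),
         per_subject = biases,
         schedule = candidate_dynamics[[1]]$schedule,
         region = region, method = method),
    class = "tac_bias_curve"
  )
}

#' Append a volume-weighted composite region
#'
#' Adds, per subject/method/parameter, a composite value computed as the
#' volume-weighted average of existing regional values — used for the whole
#' striatum (caudate + putamen).
#'
#' @param values data.frame with columns `subject`, `method`, `region`,
#'   `parameter`, `value`.
#' @param composite name of the new region.
#' @param parts character vector of constituent regions.
#' @param volumes named numeric vector of region volumes (voxels or mL).
#' @export
add_weighted_region <- function(values, composite = "striatum",
                                parts = c("caudate", "putamen"), volumes) {
  if (!all(parts %in% names(volumes))) stop("volumes must cover all parts")
  w <- volumes[parts] / sum(volumes[parts])
  sub <- values[values$region %in% parts, ]
  if (nrow(sub) == 0) return(values)
  agg <- do.call(rbind, lapply(
    split(sub, list(sub$subject, sub$method, sub$parameter), drop = TRUE),
    function(d) {
      if (nrow(d) != length(parts)) return(NULL)
      d2 <- d[1, ]
      d2$region <- composite
      d2$value <- sum(w[d$region] * d$value)
      d2
    }
  ))
  rbind(values, agg)
}

#' Accuracy/precision/agreement report
#'
#' Builds the method-comparison table: for every region, parameter and
#' non-reference method, the mean relative bias across subjects (accuracy),
#' its SD (precision), Spearman correlation and Deming slope/intercept
#' against the reference, plus per-region Friedman p across all methods and
#' Dunn-adjusted p for the comparison to the reference.
#'
#' @param values data.frame with columns `subject`, `method`, `region`,
#'   `parameter`, `value` (long format, one row per measurement).
#' @param reference method tag of the reference (default `"GE_REF"`).
#' @param alpha significance threshold for the `significant` flag.
#' @return object of class `bias_report`: a data.frame with one row per
#'   region x parameter x method.
#' @export
build_report <- function(values, reference = "GE_REF", alpha = 0.05) {
  if (!reference %in% values$method) {
    stop(sprintf("reference method '%s' missing from values", reference))
  }
  methods <- unique(values$method)
  rows <- list()
  for (par in unique(values$parameter)) {
    for (reg in unique(values$region[values$parameter == par])) {
      sub <- values[values$parameter == par & values$region == reg, ]
      wide <- stats::reshape(
        sub[, c("subject", "method", "value")],
        idvar = "subject", timevar = "method", direction = "wide"
      )
      mat <- as.matrix(wide[, -1, drop = FALSE])
      colnames(mat) <- sub("^value\\.", "", colnames(mat))
      if (!reference %in% colnames(mat)) next
      fd <- if (ncol(mat) >= 3 && nrow(mat) >= 2) {
        friedman_dunn(mat, reference)
      } else NULL
      ref_v <- mat[, reference]
      for (m in colnames(mat)) {
        cand_v <- mat[, m]
        rb <- relative_bias(cand_v, ref_v)
        dm <- if (m != reference && stats::var(ref_v) > 0 && nrow(mat) >= 3) {
          deming_regression(ref_v, cand_v)
        } else if (m == reference) list(slope = 1, intercept = 0) else {
          list(slope = NA_real_, intercept = NA_real_)
        }
        r <- if (m != reference && nrow(mat) >= 3 &&
                 stats::var(ref_v) > 0 && stats::var(cand_v) > 0) {
          spearman_r(ref_v, cand_v)
        } else if (m == reference) 1 else NA_real_
        dp <- if (!is.null(fd) && m %in% names(fd$dunn_adjusted_p)) {
          fd$dunn_adjusted_p[[m]]
        } else NA_real_
        rows[[length(rows) + 1]] <- data.frame(
          parameter = par, region = reg, method = m,
          bias_pct = mean(rb), sd_pct = stats::sd(rb),
          spearman_r = r, deming_slope = dm$slope,
          deming_intercept = dm$intercept,
          friedman_p = if (is.null(fd)) NA_real_ else fd$friedman_p,
          dunn_p = dp,
          significant = !is.na(dp) && dp < alpha,
          n = nrow(mat),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bias_report", "data.frame")
  out
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("<bias_report> %d rows (%d regions x %d methods)\n",
              nrow(x), length(unique(x$region)), length(unique(x$method))))
  print.data.frame(x, digits = 3)
  invisible(x)
}
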