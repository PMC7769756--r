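test_that("attenuation bias maps subtract voxel-wise within the mask", {
  ph <- small_phantom()
  a <- ph$truth_mu
  b <- a * 0.9
  mask <- ph$label_volume != 0L
  expect_equal(bias_map(a, a, mask)$bias, a * 0)
  bm_ab <- bias_map(a, b, mask)
  bm_ba <- bias_map(b, a, mask)
  expect_equal(bm_ab$bias, -bm_ba$bias)

  # masked mean equals independently computed difference of masked means
  soft <- ph$label_volume == 1L
  bm <- bias_map(a, b, mask, summary_masks = list(soft = soft))
  expect_equal(bm$summary[["soft"]],
               mean(a[soft & mask]) - mean(b[soft & mask]), tolerance = 1e-12)
  expect_error(bias_map(a, array(0, c(2, 2, 2))), "grid")
})

test_that("6-connected erosion shrinks a cube to its centre", {
  cube <- array(FALSE, c(9, 9, 9))
  cube[3:7, 3:7, 3:7] <- TRUE  # 5^3 solid cube
  eroded <- petmrac:::erode6(cube, 2L)
  expect_equal(sum(eroded), 1L)
  expect_true(eroded[5, 5, 5])

  # brute-force morphology oracle for a single erosion pass
  one <- petmrac:::erode6(cube, 1L)
  oracle <- array(FALSE, dim(cube))
  for (x in 2:8) for (y in 2:8) for (z in 2:8) {
    oracle[x, y, z] <- cube[x, y, z] &&
      cube[x - 1, y, z] && cube[x + 1, y, z] &&
      cube[x, y - 1, z] && cube[x, y + 1, z] &&
      cube[x, y, z - 1] && cube[x, y, z + 1]
  }
  expect_equal(one, oracle)

  expect_equal(sum(petmrac:::erode6(array(FALSE, c(4, 4, 4)), 2L)), 0L)
  # erosion output is a subset of the input
  ph <- small_phantom()
  m <- bone_mask_from_zte(zte_like_segment(ph$zte_volume,
                                           ph$label_volume != 0L),
                          erosion_px = 2)
  m0 <- bone_mask_from_zte(zte_like_segment(ph$zte_volume,
                                            ph$label_volume != 0L),
                           erosion_px = 0)
  expect_true(all(!m | m0))
})

test_that("relative bias implements the percent-difference definition", {
  expect_equal(relative_bias(2, 1), 100)
  expect_equal(relative_bias(5, 5), 0)
  expect_equal(relative_bias(0.88, 1.0), -12.0)
  expect_equal(relative_bias(c(1.1, 0.9), c(1, 1)), c(10, -10))
  expect_error(relative_bias(1, 0), "undefined")
})

test_that("Deming regression minimizes orthogonal distances", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- 2 * x + 1
  d <- deming_regression(x, y)
  expect_equal(d$slope, 2, tolerance = 1e-9)
  expect_equal(d$intercept, 1, tolerance = 1e-9)

  # brute-force orthogonal-distance search oracle (lambda = 1)
  set.seed(9)
  x <- rnorm(20, 5, 2)
  y <- 1.5 * x - 2 + rnorm(20, 0, 0.8)
  d <- deming_regression(x, y)
  odist <- function(s, b) sum((y - s * x - b)^2) / (1 + s^2)
  slopes <- seq(d$slope - 0.5, d$slope + 0.5, length.out = 201)
  ints <- seq(d$intercept - 1, d$intercept + 1, length.out = 201)
  grid_min <- min(outer(slopes, ints, Vectorize(odist)))
  expect_lte(odist(d$slope, d$intercept), grid_min + 1e-9)

  # swapping axes inverts the slope
  d_sw <- deming_regression(y, x)
  expect_equal(d_sw$slope, 1 / d$slope, tolerance = 1e-9)

  # lambda -> Inf converges to ordinary least squares of y on x
  d_inf <- deming_regression(x, y, lambda = 1e8)
  ols <- stats::lm(y ~ x)
  expect_equal(d_inf$slope, unname(stats::coef(ols)[2]), tolerance = 1e-5)
  expect_error(deming_regression(rep(1, 5), 1:5), "constant")
})

test_that("Spearman correlation uses mid-ranks", {
  x <- 1:8
  expect_equal(spearman_r(x, x^3), 1)
  expect_equal(spearman_r(x, -x), -1)
  # tied data against a manual mid-rank Pearson computation
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 6, 6, 7)
  midrank <- function(v) {
    vapply(v, function(vi) {
      mean(which(sort(v) == vi))
    }, numeric(1))
  }
  oracle <- stats::cor(midrank(xt), midrank(yt))
  expect_equal(spearman_r(xt, yt), oracle, tolerance = 1e-12)
  expect_error(spearman_r(rep(1, 5), 1:5), "constant")
})

test_that("Friedman test matches the exhaustive permutation distribution", {
  # degenerate: identical methods
  m <- matrix(rep(c(3, 1, 2), each = 3), nrow = 3)
  m[] <- 5
  fd <- friedman_dunn(m, 1)
  expect_equal(fd$statistic, 0)
  expect_equal(fd$friedman_p, 1)

  # 3 subjects x 3 methods: exact permutation p within 0.02
  vals <- matrix(c(1.2, 0.7, 1.9,
                   0.4, 1.5, 2.2,
                   0.9, 0.8, 2.0), nrow = 3, byrow = TRUE)
  obs <- friedman_dunn(vals, 1)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  stats_all <- numeric(0)
  for (p1 in perms) for (p2 in perms) for (p3 in perms) {
    pm <- rbind(vals[1, p1], vals[2, p2], vals[3, p3])
    stats_all <- c(stats_all, friedman_dunn(pm, 1)$statistic)
  }
  exact_p <- mean(stats_all >= obs$statistic - 1e-9)
  expect_equal(obs$friedman_p, exact_p, tolerance = 0.02)

  # tie-free case agrees with the base-R implementation
  set.seed(12)
  big <- matrix(rnorm(9 * 4), nrow = 9)
  ours <- friedman_dunn(big, 1)
  base_stat <- unname(stats::friedman.test(big)$statistic)
  expect_equal(ours$statistic, base_stat, tolerance = 1e-9)

  # a uniformly worst-ranked method is flagged against the reference
  worst <- cbind(ref = rnorm(9, 10, 0.1), bad = rnorm(9, 1, 0.1),
                 ok = rnorm(9, 10, 0.1), ok2 = rnorm(9, 10, 0.1))
  fd <- friedman_dunn(worst, "ref")
  expect_lt(fd$dunn_adjusted_p[["bad"]], 0.05)
  expect_error(friedman_dunn(worst[, 1, drop = FALSE]), "2 methods")
})

test_that("SUV bias curves flag constant multiplicative errors as flat", {
  ph <- small_phantom()
  truth <- assign_kinetics(ph$region_map)
  sch <- short_schedule()
  td <- true_dynamic_from_truth(ph, truth, sch)
  rl <- region_labels()
  voi <- ph$region_map == rl[["putamen"]]

  subjects <- list(td, td)
  same <- tac_bias_curves(subjects, subjects, voi)
  expect_equal(same$mean, rep(0, nframes(sch)))
  expect_equal(same$sd, rep(0, nframes(sch)))

  a <- 1.07
  scaled <- lapply(subjects, function(d) {
    d$data <- d$data * a
    d
  })
  curve <- tac_bias_curves(scaled, subjects, voi)
  expect_equal(curve$mean, rep(100 * (a - 1), nframes(sch)), tolerance = 1e-9)

  # SD per frame equals the direct across-subject SD
  jit <- lapply(seq_along(subjects), function(s) {
    d <- subjects[[s]]
    d$data <- d$data * (1 + 0.02 * s)
    d
  })
  curve2 <- tac_bias_curves(jit, subjects, voi)
  direct <- apply(curve2$per_subject, 1, stats::sd)
  expect_equal(curve2$sd, direct)
})

test_that("the bias report table has the expected structure and nulls", {
  set.seed(10)
  subjects <- 1:6
  methods <- c("GE_REF", "ZTE", "MAXPROB")
  regions <- c("caudate", "putamen")
  values <- expand.grid(subject = subjects, method = methods,
                        region = regions, parameter = "BP_ND",
                        stringsAsFactors = FALSE)
  base <- 4 + 0.3 * values$subject
  shift <- ifelse(values$method == "ZTE", 1.02,
                  ifelse(values$method == "MAXPROB", 0.9, 1))
  values$value <- base * shift * (1 + rnorm(nrow(values), 0, 0.01))
  values <- add_weighted_region(values, "striatum", c("caudate", "putamen"),
                                c(caudate = 100, putamen = 150))

  rep <- build_report(values, reference = "GE_REF")
  expect_equal(nrow(rep), 3 * 3)  # 3 regions x 3 methods
  self <- rep[rep$method == "GE_REF", ]
  expect_true(all(self$bias_pct == 0))
  expect_true(all(self$deming_slope == 1 & self$deming_intercept == 0))

  # volume-weighted striatum is consistent with direct recomputation
  cn <- values[values$region == "caudate" & values$method == "ZTE", ]
  pu <- values[values$region == "putamen" & values$method == "ZTE", ]
  st <- values[values$region == "striatum" & values$method == "ZTE", ]
  manual <- (100 * cn$value + 150 * pu$value) / 250
  expect_equal(sort(st$value), sort(manual), tolerance = 1e-12)

  expect_error(build_report(values, reference = "ABSENT"), "missing")
})
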