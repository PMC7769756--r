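# Shared 2D disk scene: 64 px, 3 mm pixels, 48 mm radius water disk.
disk_scene <- function(n = 64, p = 3, r_frac = 0.25) {
  g <- petmrac:::coord_grids(c(n, n, 1), c(p, p, p))
  r_mm <- n * p * r_frac
  list(
    n = n, p = p, r_mm = r_mm,
    disk = matrix(as.numeric(g$x[, , 1]^2 + g$y[, , 1]^2 <= r_mm^2), n),
    interior = (g$x[, , 1]^2 + g$y[, , 1]^2) <= (0.7 * r_mm)^2
  )
}

central_bin <- function(model, n, p) {
  g <- petmrac:::resolve_geometry(model, n, p)
  which.min(abs((seq_len(g$nbins) - 1 - (g$nbins - 1) / 2) * g$bw))
}

test_that("forward projection is linear and reproduces chord lengths", {
  sc <- disk_scene()
  model <- acquisition_model()
  expect_equal(forward_project(matrix(0, sc$n, sc$n), model, sc$p),
               matrix(0, model$n_bins, model$n_angles))

  set.seed(3)
  A <- matrix(runif(sc$n^2), sc$n)
  B <- matrix(runif(sc$n^2), sc$n)
  expect_equal(forward_project(A + B, model, sc$p),
               forward_project(A, model, sc$p) +
                 forward_project(B, model, sc$p),
               tolerance = 1e-12)

  v <- 7
  sino <- forward_project(sc$disk * v, model, sc$p)
  cb <- central_bin(model, sc$n, sc$p)
  # central ray through the disk: integral 2 r v, for several angles
  for (a in c(1, 21, 41, 91)) {
    expect_equal(sino[cb, a], 2 * sc$r_mm * v, tolerance = 0.02)
  }
})

test_that("attenuation factors follow the exponential chord law", {
  sc <- disk_scene()
  model <- acquisition_model()
  ones <- matrix(0, sc$n, sc$n)
  expect_equal(attenuation_factors(ones, model, sc$p),
               matrix(1, model$n_bins, model$n_angles))

  mu <- 0.096
  acf <- attenuation_factors(sc$disk * mu, model, sc$p)
  cb <- central_bin(model, sc$n, sc$p)
  expect_equal(acf[cb, 1], exp(-2 * sc$r_mm / 10 * mu), tolerance = 0.02)
  expect_true(all(acf > 0 & acf <= 1))

  # monotone in the attenuation scale
  acf2 <- attenuation_factors(sc$disk * 2 * mu, model, sc$p)
  expect_true(all(acf2 <= acf + 1e-12))
  expect_error(attenuation_factors(sc$disk * -1, model, sc$p), "nonnegative")
})

test_that("projector and backprojector are exact adjoints", {
  model <- fast_model()
  n <- 48
  set.seed(4)
  for (rep in 1:3) {
    x <- matrix(runif(n^2), n)
    y <- matrix(runif(model$n_bins * model$n_angles), model$n_bins)
    lhs <- sum(forward_project(x, model, 3) * y)
    rhs <- sum(x * back_project(y, n, model, 3))
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("frame simulation matches the expectation formula and is seeded", {
  sc <- disk_scene(n = 32, p = 3, r_frac = 0.3)
  model <- fast_model()
  sch <- short_schedule()
  act <- sc$disk * 12
  mu <- sc$disk * 0.096
  f <- 3

  counts <- simulate_frame(act, mu, f, sch, model, noise = FALSE)
  # independent expectation oracle: scale x decay x ACF x projection
  lam <- log(2) / (model$half_life * 60)
  t1 <- sch$start[f]; t2 <- t1 + sch$duration[f]
  dec <- (exp(-lam * t1) - exp(-lam * t2)) / (lam * (t2 - t1))
  expected <- model$counts_scale * sch$duration[f] * dec *
    attenuation_factors(mu, model, 3) * forward_project(act, model, 3)
  expect_equal(counts[, , 1], expected, tolerance = 1e-9)

  # doubling the frame duration doubles noise-free counts
  sch2 <- frame_schedule(c(120, sch$duration[-1]))
  c2 <- simulate_frame(act, mu, 1, sch2, model, noise = FALSE)
  c1 <- simulate_frame(act, mu, 1, sch, model, noise = FALSE)
  dec1 <- petmrac:::decay_factors(sch, model$half_life)[1]
  dec2 <- petmrac:::decay_factors(sch2, model$half_life)[1]
  expect_equal(c2 / dec2, 2 * c1 / dec1, tolerance = 1e-9)

  # identical Poisson realization for identical seeds
  n1 <- simulate_frame(act, mu, f, sch, model, seed = 77L)
  n2 <- simulate_frame(act, mu, f, sch, model, seed = 77L)
  expect_identical(n1, n2)
  expect_error(simulate_frame(act - 100, mu, f, sch, model), "nonnegative")
})

test_that("reconstruction recovers a uniform disk and conserves counts", {
  sc <- disk_scene()
  model <- acquisition_model()
  sch <- default_frame_schedule()
  act <- sc$disk * 10
  mu <- sc$disk * 0.096
  counts <- simulate_frame(act, mu, 1, sch, model, noise = FALSE)
  rec <- reconstruct_frame(counts, mu, 1, sch, model,
                           n_iterations = 100, n_subsets = 1)
  expect_true(all(rec >= 0))
  err <- (rec[, , 1][sc$interior] - 10) / 10
  expect_lt(sqrt(mean(err^2)), 0.02)

  # noise-free MLEM fixed point preserves total projected counts
  dec <- petmrac:::decay_factors(sch, model$half_life)[1]
  scale <- model$counts_scale * sch$duration[1]
  resino <- scale * attenuation_factors(mu, model, sc$p) *
    forward_project(rec[, , 1] * dec, model, sc$p)
  expect_equal(sum(resino), sum(counts), tolerance = 1e-3)

  # an all-zero sinogram reconstructs to a zero image
  z <- reconstruct_frame(counts * 0, mu, 1, sch, model)
  expect_equal(max(abs(z)), 0)
  expect_error(
    reconstruct_frame(counts[, , 1, drop = FALSE],
                      array(mu, c(sc$n, sc$n, 2)), 1, sch, model),
    "match"
  )
})

test_that("underestimated attenuation biases activity downward", {
  sc <- disk_scene(n = 48)
  model <- fast_model()
  sch <- short_schedule()
  act <- sc$disk * 10
  mu <- sc$disk * 0.12  # bone-like
  counts <- simulate_frame(act, mu, 2, sch, model, noise = FALSE)
  rec_match <- reconstruct_frame(counts, mu, 2, sch, model,
                                 n_iterations = 10, n_subsets = 10)
  rec_low <- reconstruct_frame(counts, mu * 0.8, 2, sch, model,
                               n_iterations = 10, n_subsets = 10)
  expect_lt(mean(rec_low[, , 1][sc$interior]),
            mean(rec_match[, , 1][sc$interior]))
})

test_that("matched attenuation gives unbiased VOI means across realizations", {
  sc <- disk_scene(n = 32, p = 3, r_frac = 0.3)
  model <- fast_model()
  sch <- short_schedule()
  act <- sc$disk * 30
  mu <- sc$disk * 0.096
  f <- 8  # long frame, plenty of counts
  biases <- vapply(1:10, function(s) {
    counts <- simulate_frame(act, mu, f, sch, model, seed = s)
    rec <- reconstruct_frame(counts, mu, f, sch, model,
                             n_iterations = 10, n_subsets = 10)
    mean(rec[, , 1][sc$interior]) / 30 - 1
  }, numeric(1))
  se <- stats::sd(biases) / sqrt(length(biases))
  expect_lt(abs(mean(biases)), max(3 * se, 0.01))
})

test_that("a dynamic study shares counts across candidate maps", {
  ph <- small_phantom()
  truth <- assign_kinetics(ph$region_map)
  sch <- short_schedule()
  td <- true_dynamic_from_truth(ph, truth, sch)
  model <- fast_model()
  z <- which.max(apply(ph$region_map > 0, 3, sum))
  slices <- z  # single representative slice keeps this fast
  maps <- list(A = mu_map(ph$truth_mu), B = mu_map(ph$truth_mu))
  recs <- simulate_dynamic_study(td, ph$truth_mu, maps, model, seed = 2L,
                                 noise = TRUE, n_iterations = 6,
                                 n_subsets = 10, slices = slices)
  expect_equal(dim(recs$A$data)[4], nframes(sch))
  # identical candidate maps give identical reconstructions
  expect_identical(recs$A$data, recs$B$data)
  expect_error(simulate_dynamic_study(td, ph$truth_mu, list(), model),
               "empty")
})
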