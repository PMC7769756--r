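test_that("the default framing scheme covers 80 minutes in 22 frames", {
  sch <- default_frame_schedule()
  expect_equal(nframes(sch), 22L)
  expect_equal(sum(sch$duration), 80 * 60)
  expect_equal(sch$duration[1:6], c(rep(60, 4), rep(120, 2)))
  # contiguous and nonoverlapping
  expect_equal(sch$start[-1], (sch$start + sch$duration)[-22])
  expect_error(frame_schedule(c(60, -10)), "> 0")
})

test_that("the SRTM forward model matches its analytic convolution", {
  sch <- default_frame_schedule()
  # R1 = 1, k2 = k2a collapses to the reference curve
  ref <- reference_input()
  t_min <- petmrac:::dense_grid(sch)
  cr_frames <- petmrac:::frame_average(ref(t_min), t_min, sch)
  tc <- srtm_forward(c(R1 = 1, k2 = 0.3, k2a = 0.3), ref, sch)
  expect_equal(tc$value, cr_frames, tolerance = 1e-9)

  # monoexponential reference: closed-form convolution oracle
  beta <- 0.1
  crf <- function(t) exp(-beta * t)
  for (k2a in c(0.05, 0.2, 0.45)) {
    tc <- srtm_forward(c(R1 = 0.5, k2 = 0.3, k2a = k2a), crf, sch)
    conv_cf <- (exp(-beta * t_min) - exp(-k2a * t_min)) / (k2a - beta)
    ct_cf <- 0.5 * crf(t_min) + (0.3 - 0.5 * k2a) * conv_cf
    oracle <- petmrac:::frame_average(ct_cf, t_min, sch)
    expect_equal(tc$value, oracle, tolerance = 1e-6)
  }

  # linear in the reference amplitude
  tc1 <- srtm_forward(c(R1 = 0.8, k2 = 0.25, k2a = 0.1), ref, sch)
  tc3 <- srtm_forward(c(R1 = 0.8, k2 = 0.25, k2a = 0.1),
                      function(t) 3 * ref(t), sch)
  expect_equal(tc3$value, 3 * tc1$value, tolerance = 1e-9)
  expect_error(srtm_forward(c(R1 = 1, k2 = -1, k2a = 0.1), ref, sch), "> 0")
})

test_that("basis curves match a brute-force trapezoidal convolution", {
  sch <- frame_schedule(c(rep(60, 4), rep(120, 3)))  # 10 min, cheap oracle
  ref <- reference_input()
  basis <- make_basis(ref, sch, n_theta = 5)
  expect_equal(length(basis$theta), 5)
  expect_true(all(diff(basis$theta) > 0))

  dt_min <- 0.25 / 60
  t_min <- petmrac:::dense_grid(sch, 0.25)
  cr <- ref(t_min)
  for (i in seq_along(basis$theta)) {
    th <- basis$theta[i]
    # direct O(N^2) trapezoidal convolution
    conv <- vapply(seq_along(t_min), function(n) {
      if (n == 1) return(0)
      integrand <- cr[1:n] * exp(-th * (t_min[n] - t_min[1:n]))
      (sum(integrand) - (integrand[1] + integrand[n]) / 2) * dt_min
    }, numeric(1))
    oracle <- petmrac:::frame_average(conv, t_min, sch)
    expect_equal(basis$B[, i], oracle, tolerance = 1e-6)
  }
  # convolution from zero: the first frame value is small
  expect_lt(basis$B[1, 1] / max(basis$B[, 1]), 0.2)
  expect_error(make_basis(ref, sch, theta_min = -1), "theta")
})

test_that("basis-function fitting recovers parameters and minimizes RSS", {
  sch <- default_frame_schedule()
  ref <- reference_input()
  basis <- make_basis(ref, sch)

  # self-fit of the reference curve
  t_min <- petmrac:::dense_grid(sch)
  ref_tac <- tac(petmrac:::frame_average(ref(t_min), t_min, sch), sch)
  fit <- rpm_fit(ref_tac, basis)
  expect_equal(fit$R1, 1, tolerance = 1e-6)
  expect_equal(fit$BP_ND, 0, tolerance = 1e-6)

  # exact recovery when k2a sits on the theta grid
  th <- basis$theta[37]
  tc <- srtm_forward(c(R1 = 0.9, k2 = 0.3, k2a = th), ref, sch)
  fit <- rpm_fit(tc, basis)
  expect_equal(fit$R1, 0.9, tolerance = 1e-6)
  expect_equal(fit$k2, 0.3, tolerance = 1e-6)
  expect_equal(fit$BP_ND, 0.3 / th - 1, tolerance = 1e-6)

  # chosen theta beats an independent per-theta least-squares (lm) search
  set.seed(5)
  noisy <- tac(tc$value * (1 + rnorm(22, 0, 0.05)), sch)
  fit_n <- rpm_fit(noisy, basis)
  rss_lm <- vapply(seq_along(basis$theta), function(i) {
    sum(stats::lm(noisy$value ~ 0 + basis$cr_frames + basis$B[, i])$residuals^2)
  }, numeric(1))
  expect_lte(fit_n$rss, min(rss_lm) + 1e-9)
  expect_equal(fit_n$rss, min(rss_lm), tolerance = 1e-6)
})

test_that("fits are scale invariant with the reference and bounded below", {
  sch <- default_frame_schedule()
  ref <- reference_input()
  basis <- make_basis(ref, sch)
  tc <- srtm_forward(c(R1 = 0.9, k2 = 0.3, k2a = 0.07), ref, sch)
  fit0 <- rpm_fit(tc, basis)

  # global scaling of target and reference leaves R1 and BP_ND unchanged
  for (a in c(0.5, 2)) {
    basis_a <- make_basis(function(t) a * ref(t), sch)
    fit_a <- rpm_fit(tac(a * tc$value, sch), basis_a)
    expect_equal(fit_a$R1, fit0$R1, tolerance = 1e-6)
    expect_equal(fit_a$BP_ND, fit0$BP_ND, tolerance = 1e-6)
  }

  # target-only scaling maps R1 -> a R1 and BP_ND -> a (BP_ND + 1) - 1
  a <- 1.2
  fit_t <- rpm_fit(tac(a * tc$value, sch), basis)
  expect_equal(fit_t$R1, a * fit0$R1, tolerance = 1e-4)
  expect_equal(fit_t$BP_ND, a * (fit0$BP_ND + 1) - 1, tolerance = 1e-3)

  # BP_ND never falls below -1, even for pathological input
  set.seed(6)
  for (r in 1:20) {
    y <- pmax(rnorm(22, 2, 2), 0) - 1.5
    f <- rpm_fit(tac(y, sch), basis)
    expect_gte(f$BP_ND, -1)
  }
  expect_error(rpm_fit(tac(rep(1, 22), sch),
                       make_basis(function(t) 0 * t, sch)),
               "degenerate")
})

test_that("binding potential survives counting noise in a high-BP region", {
  sch <- default_frame_schedule()
  ref <- reference_input()
  basis <- make_basis(ref, sch)
  true_bp <- 0.3 / 0.07 - 1
  tc <- srtm_forward(c(R1 = 0.9, k2 = 0.3, k2a = 0.07), ref, sch)
  errs <- vapply(1:50, function(s) {
    noisy <- tac_poisson_noise(tc, seed = s)
    abs(rpm_fit(noisy, basis)$BP_ND / true_bp - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("regional TAC extraction is linear and SUV uses the dose constant", {
  ph <- small_phantom()
  truth <- assign_kinetics(ph$region_map)
  sch <- short_schedule()
  td <- true_dynamic_from_truth(ph, truth, sch)
  rl <- region_labels()
  voi <- ph$region_map == rl[["putamen"]]
  t1 <- extract_tac(td, voi)

  # mean of single-voxel TACs equals the VOI TAC
  idx <- which(voi)
  per_vox <- vapply(idx[1:10], function(i) extract_tac(td, i)$value,
                    numeric(nframes(sch)))
  expect_equal(extract_tac(td, idx[1:10])$value, rowMeans(per_vox),
               tolerance = 1e-12)

  s <- to_suv(tac(rep(10, nframes(sch)), sch), dose_per_kg = 5)
  expect_equal(s$suv, rep(2, nframes(sch)))
  expect_error(extract_tac(td, voi & FALSE), "empty")
})

test_that("parametric maps agree with regional fits and respect the mask", {
  ph <- small_phantom()
  truth <- assign_kinetics(ph$region_map)
  sch <- default_frame_schedule()
  td <- true_dynamic_from_truth(ph, truth, sch)
  rl <- region_labels()
  ref_voi <- ph$region_map == rl[["cerebellum-GM"]]
  brain <- ph$label_volume == 1L
  maps <- fit_parametric_maps(td, ref_voi, brain)

  expect_true(all(maps$BP_ND[!brain] == 0))
  expect_true(all(maps$R1[!brain] == 0))

  # noise-free voxel fits agree with the region-level fit
  voi <- ph$region_map == rl[["putamen"]]
  basis <- maps$basis
  reg_fit <- rpm_fit(extract_tac(td, voi), basis)
  expect_equal(median(maps$BP_ND[voi]), reg_fit$BP_ND, tolerance = 0.01)
  # and with the ground truth (k2a off-grid: grid-resolution tolerance)
  expect_equal(median(maps$BP_ND[voi]),
               truth$BP_ND[truth$region == "putamen"], tolerance = 0.03)
  # reference region itself: R1 = 1, BP_ND = 0
  expect_equal(median(maps$R1[ref_voi]), 1, tolerance = 1e-3)
  expect_equal(median(maps$BP_ND[ref_voi]), 0, tolerance = 1e-3)
  expect_error(fit_parametric_maps(td, ref_voi, brain & FALSE), "empty")
})
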