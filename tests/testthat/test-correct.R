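test_that("ghost bands are the phase-encode complement of the object extent", {
  m <- matrix(FALSE, 32, 32)
  m[, 11:21] <- TRUE            # object at 0-based PE rows 10..20
  b <- build_ghost_bands(m)
  expect_setequal(b$band_cols, c(1:10, 22:32))
  expect_false(any(b$mask & m))
  b2 <- build_ghost_bands(m, margin_rows = 2L)
  expect_setequal(b2$band_cols, c(1:8, 24:32))
  all_rows <- matrix(TRUE, 32, 32)
  expect_error(build_ghost_bands(all_rows), "supply bands manually")
  # dual phantom under a single enclosing ROI
  dual <- matrix(FALSE, 32, 32)
  dual[, 7:13] <- TRUE; dual[, 19:26] <- TRUE
  expect_setequal(build_ghost_bands(dual)$band_cols, c(1:6, 27:32))
})

test_that("Ahn unwrapping recovers wrapped linear phase ramps", {
  n <- 64
  slope_ok <- 0.1 * (0:(n - 1))
  u1 <- phase_unwrap_1d(complex(modulus = 1, argument = slope_ok))
  expect_equal(u1$phase, slope_ok, tolerance = 1e-12)
  truth <- 2.5 * (0:(n - 1))
  wrapped <- complex(modulus = 1, argument = truth)  # Arg wraps into (-pi, pi]
  u2 <- phase_unwrap_1d(wrapped)
  expect_equal(u2$phase, truth, tolerance = 1e-12)
  # single wrap past +pi
  ph <- c(rep(pi - 0.01, 3), rep(-pi + 0.01, 3))
  u3 <- phase_unwrap_1d(complex(modulus = 1, argument = ph))
  expect_equal(u3$phase, c(rep(pi - 0.01, 3), rep(pi + 0.01, 3)), tolerance = 1e-12)
  # zero-magnitude runs carry the last phase forward and are flagged
  s <- complex(modulus = c(1, 1, 0, 0, 1), argument = c(0.2, 0.4, 0, 0, 0.8))
  u4 <- phase_unwrap_1d(s)
  expect_equal(u4$phase[3:4], c(0.4, 0.4))
  expect_equal(u4$carried, c(FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("reference-scan estimation recovers the true pair on noiseless data", {
  img <- make_phantom(default_phantom())
  c0 <- phase_coeffs(0.25, 0.40, canonicalize = FALSE)
  ref <- acquire_reference(img, acquisition_params(coeffs = c0, noise_sd = 0,
                                                   t2star = NULL))
  est <- estimate_from_reference(ref)
  expect_true(all(abs(est$alpha_j - 0.25) < 1e-6))
  expect_true(all(abs(est$beta_j - 0.40) < 1e-6))
  ref0 <- acquire_reference(img, acquisition_params(coeffs = phase_coeffs(0, 0),
                                                    noise_sd = 0, t2star = NULL))
  est0 <- estimate_from_reference(ref0)
  expect_true(all(abs(est0$alpha_j) < 1e-9))
  expect_true(all(abs(est0$beta_j) < 1e-9))
})

test_that("reference-scan estimation is unbiased under noise", {
  img <- make_phantom(default_phantom())
  c0 <- phase_coeffs(0.25, 0.40, canonicalize = FALSE)
  # noise level giving projection SNR around 20
  ests <- vapply(1:60, function(s) {
    p <- acquisition_params(coeffs = c0, noise_sd = 3, seed = s, t2star = NULL)
    e <- average_coeffs(estimate_from_reference(acquire_reference(img, p)))
    c(e$alpha, e$beta)
  }, numeric(2))
  se <- apply(ests, 1, sd) / sqrt(ncol(ests))
  expect_lt(abs(mean(ests[1, ]) - 0.25), 3 * se[1] + 1e-4)
  expect_lt(abs(mean(ests[2, ]) - 0.40), 3 * se[2] + 1e-4)
})

test_that("integrated-echo estimation handles degenerate echoes", {
  img <- make_phantom(default_phantom())
  line <- epighost:::ft2(img$data)[, 17]
  same <- cbind(line, line, line)
  est <- estimate_from_integrated_echoes(same)
  expect_equal(est$alpha, 0, tolerance = 1e-12)
  expect_equal(est$beta, 0, tolerance = 1e-12)
  decayed <- cbind(line, 0.9 * line, 0.81 * line)  # magnitude decay, no phase
  est2 <- estimate_from_integrated_echoes(decayed)
  expect_equal(est2$alpha, 0, tolerance = 1e-12)
  expect_equal(est2$beta, 0, tolerance = 1e-12)
  expect_error(estimate_from_integrated_echoes(cbind(line)), "at least 2")
})

test_that("gyromagnetic rescaling follows the gamma and FOV ratios", {
  c0 <- phase_coeffs(0.3, 0.5, canonicalize = FALSE)
  expect_equal(scale_reference_coeffs(c0, 1, 1), c0)
  s <- scale_reference_coeffs(c0, gamma_ratio = 0.2515, fov_ratio = 0.25)
  expect_equal(s$alpha, 0.3 * 0.2515, tolerance = 1e-12)
  expect_equal(s$beta, 0.5 * 1.006, tolerance = 1e-12)
  back <- scale_reference_coeffs(s, gamma_ratio = 1 / 0.2515, fov_ratio = 4)
  expect_equal(back$alpha, c0$alpha, tolerance = 1e-12)
  expect_equal(back$beta, c0$beta, tolerance = 1e-12)
  expect_error(scale_reference_coeffs(c0, -1, 1), "positive")
})

test_that("the 1D search recovers on-grid corruption exactly and off-grid within a step", {
  fx <- disk_fixture()
  cfg <- search_config()
  ct_on <- phase_coeffs(grid_point(38), grid_point(81), canonicalize = FALSE)
  k <- acquire_epi(fx$img, acquisition_params(coeffs = ct_on, noise_sd = 0,
                                              t2star = NULL))
  res <- search_1d(k, fx$bands, cfg)
  expect_identical(res$coeffs$alpha, grid_point(38))
  expect_identical(res$coeffs$beta, grid_point(81))
  # exhaustiveness: returned objective is the grid minimum
  expect_equal(res$band_mean, min(res$objective))
  # off-grid corruption
  ct_off <- phase_coeffs(0.333, -0.617, canonicalize = FALSE)
  k2 <- acquire_epi(fx$img, acquisition_params(coeffs = ct_off, noise_sd = 0,
                                               t2star = NULL))
  res2 <- search_1d(k2, fx$bands, cfg)
  expect_lt(abs(res2$coeffs$alpha - 0.333), grid_step(cfg))
  expect_lt(abs(res2$coeffs$beta + 0.617), grid_step(cfg))
})

test_that("the 1D search leaves ghost-free input essentially untouched", {
  fx <- disk_fixture()
  cfg <- search_config()
  k <- acquire_epi(fx$img, acquisition_params(coeffs = phase_coeffs(0, 0),
                                              noise_sd = 0, t2star = NULL))
  res <- search_1d(k, fx$bands, cfg)
  # zero is not on the even-sized grid: the best the search can do is the
  # nearest grid point, whose correction perturbs the bands by less than one
  # grid-step's worth of ghost
  expect_lte(abs(res$coeffs$alpha), grid_step(cfg))
  expect_lte(abs(res$coeffs$beta), grid_step(cfg))
  base <- mean(magnitude(reconstruct(k))[fx$bands$mask])
  expect_lt(abs(res$band_mean - base), sin(grid_step(cfg)) * max(magnitude(fx$img)))
})

test_that("the 2D search is consistent with a 1D corruption model", {
  fx <- disk_fixture()
  cfg <- search_config(n_steps = 51L)  # odd count puts 0 on the grid; coarse = quick
  ct <- phase_coeffs(grid_point(20, cfg), grid_point(35, cfg), canonicalize = FALSE)
  k <- acquire_epi(fx$img, acquisition_params(coeffs = ct, noise_sd = 0,
                                              t2star = NULL,
                                              lines_before_center = 16L))
  res <- search_2d(k, fx$bands, cfg)
  expect_equal(res$coeffs$beta_y, 0, tolerance = 1e-12)
  xn <- (0:31 - 16) / 16
  expected <- ct$alpha + ct$beta * xn
  # only readout rows with object signal constrain theta; the rest see no
  # ghost energy and fall to the tie-break
  signal_rows <- which(rowSums(magnitude(fx$img)) > 0)
  expect_true(all(abs(res$coeffs$theta_col[signal_rows] - expected[signal_rows])
                  <= grid_step(cfg) + 1e-12))
  # residual ghosting is theta-grid quantization limited (the per-row phase
  # alpha + beta*x falls between grid points) and shrinks with the step size
  res_fine <- search_2d(k, fx$bands, search_config(n_steps = 201L))
  expect_lt(ghosting_level(magnitude(res_fine$corrected), fx$rois), 0.5)
  expect_lt(ghosting_level(magnitude(res_fine$corrected), fx$rois),
            ghosting_level(magnitude(res$corrected), fx$rois))
})

test_that("reference, echo and search estimates agree on noiseless data", {
  fx <- disk_fixture()
  ct <- default_corruption()
  p <- acquisition_params(coeffs = ct, noise_sd = 0, t2star = NULL)
  ref_est <- average_coeffs(estimate_from_reference(acquire_reference(fx$img, p)))
  echo_est <- estimate_from_integrated_echoes(
    acquire_integrated_echoes(fx$img, p)$echoes)
  search_est <- search_1d(acquire_epi(fx$img, p), fx$bands)$coeffs
  step <- grid_step(search_config())
  for (pair in list(c(ref_est$alpha, echo_est$alpha),
                    c(ref_est$alpha, search_est$alpha)))
    expect_lt(abs(pair[1] - pair[2]), step)
  for (pair in list(c(ref_est$beta, echo_est$beta),
                    c(ref_est$beta, search_est$beta)))
    expect_lt(abs(pair[1] - pair[2]), step)
})

test_that("workflow transfer corrects every measurable frame of a noiseless series", {
  # on-grid corruption and full sampling: the searched pair is exact, so the
  # transferred correction must drive ghosting to numerical zero
  ct <- phase_coeffs(grid_point(68), grid_point(77), canonicalize = FALSE)
  p <- acquisition_params(coeffs = ct, noise_sd = 0, t2star = NULL,
                          lines_before_center = 16L)
  series <- make_dynamic_series(p = p, n_frames = 6L)
  wf <- apply_workflow(series, snr_floor = 0)
  rois <- build_roi_set(wf$object_mask)
  for (met in names(wf$corrected)) {
    for (t in seq_along(wf$corrected[[met]])) {
      g <- tryCatch(ghosting_level(magnitude(wf$corrected[[met]][[t]]), rois),
                    error = function(e) NULL)   # zero-signal frames: undefined
      if (!is.null(g)) expect_lt(g, 0.1)
    }
  }
})

test_that("searching on a noise-only frame warns but still runs", {
  p <- acquisition_params(noise_sd = 1, seed = 8L)
  series <- make_dynamic_series(p = p, n_frames = 5L)
  expect_warning(wf <- apply_workflow(series, frame_selector = 1L),
                 "below the reliability floor")
  expect_s3_class(wf$coeffs, "phase_coeffs")
})
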