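test_that("phantom rasterization matches disk area and superposes", {
  disk <- make_phantom(default_phantom())
  # a disk of radius 0.5 on the [-1,1)^2 grid covers ~pi/16 of the pixels
  expect_equal(mean(magnitude(disk) > 0), pi / 16, tolerance = 0.05)
  two <- phantom_spec(list(shape(-0.4, -0.4, 0.2, 0.2, 1),
                           shape(0.4, 0.4, 0.2, 0.2, 2)), c(32L, 32L))
  one_a <- make_phantom(phantom_spec(list(shape(-0.4, -0.4, 0.2, 0.2, 1)), c(32L, 32L)))
  one_b <- make_phantom(phantom_spec(list(shape(0.4, 0.4, 0.2, 0.2, 2)), c(32L, 32L)))
  expect_equal(make_phantom(two)$data, one_a$data + one_b$data)
  expect_true(all(magnitude(make_phantom(phantom_spec(list(), c(32L, 32L)))) == 0))
  expect_error(phantom_spec(list(shape(0.9, 0, 0.5)), c(32L, 32L)), "beyond the FOV")
})

test_that("noise-free full-sampling acquisition reconstructs the object exactly", {
  img <- make_phantom(default_phantom())
  p <- acquisition_params(coeffs = phase_coeffs(0, 0), lines_before_center = 16L,
                          noise_sd = 0, t2star = NULL)
  rec <- reconstruct(acquire_epi(img, p))
  expect_lt(max(Mod(rec$data - img$data)), 1e-12)
})

test_that("acquisition is deterministic under a fixed seed and noise stays off zero-filled lines", {
  img <- make_phantom(default_phantom())
  p <- acquisition_params(noise_sd = 2, seed = 42L)
  k1 <- acquire_epi(img, p); k2 <- acquire_epi(img, p)
  expect_identical(k1$data, k2$data)
  expect_true(all(k1$data[, !k1$acquired_mask] == 0))
  k3 <- acquire_epi(img, acquisition_params(noise_sd = 2, seed = 43L))
  expect_gt(max(Mod(k1$data - k3$data)), 0)
})

test_that("simulated corruption produces the half-FOV ghost the oracle predicts", {
  fx <- disk_fixture()
  c0 <- phase_coeffs(0.4, 0.3, canonicalize = FALSE)
  p <- acquisition_params(coeffs = c0, lines_before_center = 16L, noise_sd = 0,
                          t2star = NULL)
  rec <- reconstruct(acquire_epi(fx$img, p))
  expect_gt(ghosting_level(magnitude(rec), fx$rois), 5)
  oracle <- closed_form_ghost(fx$img, c0)
  expect_lt(max(Mod(rec$data - oracle$data)), 1e-10)
})

test_that("reference scans repeat the ky=0 projection with alternating corruption", {
  img <- make_phantom(default_phantom())
  p0 <- acquisition_params(coeffs = phase_coeffs(0, 0), noise_sd = 0, t2star = NULL)
  ref <- acquire_reference(img, p0)
  acq <- which(ref$acquired_mask)
  evens <- acq[acq %% 2 == 1]  # 1-based odd columns = even 0-based lines
  odds <- acq[acq %% 2 == 0]
  expect_lt(max(Mod(sweep(ref$data[, evens], 1, ref$data[, evens[1]], `-`))), 1e-12)
  expect_lt(max(Mod(sweep(ref$data[, odds], 1, ref$data[, odds[1]], `-`))), 1e-12)
  # with corruption, adjacent hybrid lines differ in phase by 2*theta(x)
  c0 <- phase_coeffs(0.25, 0.40, canonicalize = FALSE)
  ref2 <- acquire_reference(img, acquisition_params(coeffs = c0, noise_sd = 0,
                                                    t2star = NULL))
  h <- epighost:::ift_readout(ref2$data)
  j <- acq[1]  # 0-based index j-1
  dphi <- Arg(h[, j + 1] * Conj(h[, j]))
  xn <- (0:31 - 16) / 16
  expected <- (if ((j - 1) %% 2 == 0) -2 else 2) * (0.25 + 0.40 * xn)
  keep <- Mod(h[, j]) > 0.1 * max(Mod(h[, j]))
  wrap <- function(v) Arg(exp(1i * v))
  expect_lt(max(abs(wrap(dphi[keep] - expected[keep]))), 1e-9)
})

test_that("a gamma-scaled 1H reference recovers the 13C coefficients after rescaling", {
  img <- make_phantom(default_phantom())
  c0 <- phase_coeffs(0.25, 0.40, canonicalize = FALSE)
  p <- acquisition_params(coeffs = c0, noise_sd = 0, t2star = NULL)
  ref_h <- acquire_reference(img, p, nucleus = "H1",
                             gamma_ratio = 0.2515, fov_ratio = 0.25)
  est_h <- average_coeffs(estimate_from_reference(ref_h))
  est_c <- scale_reference_coeffs(est_h, gamma_ratio = 0.2515, fov_ratio = 0.25)
  expect_equal(est_c$alpha, 0.25, tolerance = 1e-6)
  expect_equal(est_c$beta, 0.40, tolerance = 1e-6)
})

test_that("integrated echoes shift the imaging train and pay the documented T2* penalty", {
  img <- make_phantom(default_phantom())
  c0 <- phase_coeffs(0.2, 0.3, canonicalize = FALSE)
  p_nodecay <- acquisition_params(coeffs = c0, noise_sd = 0, t2star = NULL)
  ie <- acquire_integrated_echoes(img, p_nodecay, n_echoes = 3L)
  plain <- acquire_epi(img, p_nodecay)
  expect_lt(max(Mod(ie$kspace$data - plain$data)), 1e-12)
  p_decay <- acquisition_params(coeffs = c0, noise_sd = 0, t2star = 0.020,
                                echo_spacing = 552e-6)
  ie2 <- acquire_integrated_echoes(img, p_decay, n_echoes = 3L)
  plain2 <- acquire_epi(img, p_decay)
  dc <- 17  # centre line
  ratio <- Mod(ie2$kspace$data[17, dc]) / Mod(plain2$data[17, dc])
  expect_equal(ratio, exp(-3 * 552e-6 / 0.020), tolerance = 1e-10)
  expect_equal(exp(-3 * 552e-6 / 0.020), 0.920, tolerance = 1e-3)
  est <- estimate_from_integrated_echoes(ie2$echoes)
  expect_equal(est$alpha, 0.2, tolerance = 1e-9)
  expect_equal(est$beta, 0.3, tolerance = 1e-9)
  expect_error(acquire_integrated_echoes(img, p_decay, n_echoes = 1L),
               "at least 2")
})

test_that("dynamic series follow the metabolite curves deterministically", {
  p <- acquisition_params(noise_sd = 1, seed = 5L)
  s1 <- make_dynamic_series(p = p, n_frames = 6L)
  s2 <- make_dynamic_series(p = p, n_frames = 6L)
  for (t in 1:6)
    expect_identical(s1$frames$lactate[[t]]$data, s2$frames$lactate[[t]]$data)
  # lactate peaks where its curve does
  mask <- phantom_mask(tumour_phantom())
  nm <- noise_mask_for(mask)
  snrs <- vapply(s1$frames$lactate, function(k)
    snr(magnitude(reconstruct(k)), mask, nm), numeric(1))
  expect_equal(which.max(snrs), which.max(s1$curves$lactate))
  # all-zero curves give pure-noise frames
  s0 <- make_dynamic_series(curves = list(pyruvate = rep(0, 3), lactate = rep(0, 3)),
                            p = p, n_frames = 3L)
  m <- magnitude(reconstruct(s0$frames$pyruvate[[1]]))
  expect_gt(sd(m), 0)
  expect_lt(mean(m[mask]) / sd(m[nm]), 3)  # no object signal above noise
})
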