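test_that("evaluation ranges mask exactly the stated closed intervals", {
  rng <- evaluation_ranges()
  ppm <- c(0.19, 0.2, 1.2, 1.21, 1.5, 1.79, 1.8, 3.88, 3.89)
  expect_identical(range_mask(ppm, rng),
                   c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE,
                     FALSE))
  expect_error(evaluation_ranges(list(c(1, 2), c(1.5, 3))), "overlap")
})

test_that("noiseless mixtures are recovered and masked bands are inert", {
  basis <- tiny_basis()
  truth <- c(NAA = 1.0, tCr = 2.0, tCho = 0.5, MM = 1.2)
  sp <- make_mixture_spectrum(basis, truth, shift_hz = 3, damp_hz = 6,
                              phase = 0.4)
  ft <- fit_spectrum(sp, basis, noise_sd = 1e-4)
  expect_true(all(abs(ft$amplitudes - truth) / truth < 1e-4))
  expect_equal(ft$global_shift_hz, 3, tolerance = 1e-3)
  expect_equal(ft$extra_damping_hz, 6, tolerance = 1e-3)
  expect_equal(ft$zero_order_phase, 0.4, tolerance = 1e-3)
  expect_true(all(ft$amplitudes >= 0))

  # arbitrary extra signal confined to the excluded 1.4-1.6 ppm band does
  # not move the estimates
  contaminated <- sp
  band <- basis$ppm_axis >= 1.4 & basis$ppm_axis <= 1.6
  contaminated[band] <- contaminated[band] + 50 * (1 + 1i)
  ft2 <- fit_spectrum(contaminated, basis, noise_sd = 1e-4)
  expect_equal(ft2$amplitudes, ft$amplitudes, tolerance = 1e-6)

  # residual at the optimum is no worse than at the generating parameters
  set.seed(42)
  noisy <- sp + complex(real = rnorm(length(sp), 0, 0.05),
                        imaginary = rnorm(length(sp), 0, 0.05))
  ft3 <- fit_spectrum(noisy, basis, noise_sd = 0.05)
  mask <- range_mask(basis$ppm_axis, evaluation_ranges())
  model_true <- make_mixture_spectrum(basis, truth, 3, 6, 0.4)
  expect_lte(ft3$resid2, sum(Mod((noisy - model_true)[mask])^2))

  expect_error(fit_spectrum(sp * NaN, basis), "non-finite")
})

test_that("CRLBs scale with noise, decouple for orthogonal lines, and match a
           finite-difference oracle", {
  basis <- tiny_basis()
  truth <- c(NAA = 1.0, tCr = 2.0, tCho = 0.5, MM = 1.2)
  sp <- make_mixture_spectrum(basis, truth, 2, 5, 0.1)
  f1 <- fit_spectrum(sp, basis, noise_sd = 0.05)
  f2 <- fit_spectrum(sp, basis, noise_sd = 0.10)
  expect_equal(f2$crlb_percent / f1$crlb_percent,
               rep(2, 4), ignore_attr = TRUE, tolerance = 1e-6)

  # orthogonal (well-separated) two-compound basis: the amplitude Fisher
  # block is diagonal, so the absolute CRLB of one compound neither
  # depends on the other amplitude nor on the other compound's presence
  sep <- build_basis_set(list(A = resonance(2.0, 1, 0.06),
                              B = resonance(3.5, 1, 0.06)),
                         tiny_acquisition())
  maskS <- range_mask(sep$ppm_axis, evaluation_ranges())
  Bsp <- fidmrsi:::masked_basis_matrix(
    fidmrsi:::masked_model_precompute(sep, maskS), 0, 0)
  for (amps in list(c(A = 1, B = 1), c(A = 1, B = 5))) {
    both <- crlb_percent(Bsp, 0.05, amps)
    alone <- crlb_percent(Bsp[, 1, drop = FALSE], 0.05, amps["A"])
    expect_equal(both[["A"]], alone[["A"]], tolerance = 1e-3)
  }

  # analytic Jacobian vs central finite differences
  mask <- range_mask(basis$ppm_axis, evaluation_ranges())
  par <- c(f1$global_shift_hz, f1$extra_damping_hz, f1$zero_order_phase)
  model_of <- function(a, shift, damp, phase)
    make_mixture_spectrum(basis, a, shift, damp, phase)[mask]
  J <- fidmrsi:::fit_jacobian(basis, mask, par, f1$amplitudes)
  h <- 1e-6
  for (j in seq_along(truth)) {
    da <- f1$amplitudes; db <- f1$amplitudes
    da[j] <- da[j] + h; db[j] <- db[j] - h
    fd <- (model_of(da, par[1], par[2], par[3]) -
             model_of(db, par[1], par[2], par[3])) / (2 * h)
    expect_lt(max(Mod(J[, j] - fd)) / max(Mod(fd)), 1e-2)
  }
  fd_shift <- (model_of(f1$amplitudes, par[1] + h, par[2], par[3]) -
                 model_of(f1$amplitudes, par[1] - h, par[2], par[3])) / (2 * h)
  expect_lt(max(Mod(J[, ".shift"] - fd_shift)) / max(Mod(fd_shift)), 1e-2)

  expect_error(crlb_percent(J, 0, f1$amplitudes), "noise_sd")
})

test_that("SNR estimators agree and respond to noise as expected", {
  basis <- tiny_basis()
  truth <- c(NAA = 1.0, tCr = 2.0, tCho = 0.5, MM = 1.2)
  sp <- make_mixture_spectrum(basis, truth, 0, 8, 0)
  f <- fit_spectrum(sp, basis, noise_sd = 0.05)

  snr1 <- estimate_snr(f, basis, noise_sd = 0.05)
  snr2 <- estimate_snr(f, basis, noise_sd = 0.10)
  expect_equal(snr1 / snr2, 2, tolerance = 1e-9)

  # a 4.9-SNR voxel fails the mask threshold
  thr <- quality_thresholds()
  expect_lt(4.9, thr$snr_min)

  # pseudo-replica estimate within 10% of the known noise SD (100 replicas)
  set.seed(31)
  sdt <- 0.07
  prescans <- matrix(complex(real = rnorm(basis$n_points * 24, 0, sdt),
                             imaginary = rnorm(basis$n_points * 24, 0, sdt)),
                     basis$n_points, 24)
  snr_pr <- estimate_snr(f, basis, method = "pseudo_replica",
                         prescans = prescans, n_replicas = 100)
  snr_known <- estimate_snr(f, basis, noise_sd = sdt)
  expect_lt(abs(snr_pr - snr_known) / snr_known, 0.10)

  expect_error(estimate_snr(f, basis, noise_sd = 0), "zero noise")
})

test_that("linewidth estimate follows the closed form", {
  # T2*_eff = 100 ms at 297.2 MHz: 3.183 Hz = 0.0107 ppm
  acq <- tiny_acquisition()
  b100 <- build_basis_set(list(tCr = resonance(3.027, 3, 0.1),
                               NAA = resonance(2.008, 3, 0.1)), acq)
  sp <- make_mixture_spectrum(b100, c(tCr = 1, NAA = 1), 0, 0, 0)
  f <- fit_spectrum(sp, b100, noise_sd = 1e-4)
  expect_equal(f$extra_damping_hz, 0, tolerance = 1e-3)
  expect_equal(estimate_fwhm(f, b100), 1 / (pi * 0.1) / 297.2,
               tolerance = 1e-3)
  expect_equal(estimate_fwhm(f, b100), 0.0107, tolerance = 1e-3)

  # a 0.16-ppm linewidth fails the mask threshold
  expect_gt(0.16, quality_thresholds()$fwhm_max_ppm)
})

test_that("water-reference fitting recovers amplitude and flags dead voxels", {
  wb <- build_water_basis()
  acq <- water_acquisition()
  t_eff <- (seq_len(wb$n_points) - 1) / wb$sampling_bandwidth +
    wb$acquisition_delay
  amp <- 1234.5
  fid <- amp * wb$signals[, 1] * exp((2i * pi * 1.5 - pi * 9) * t_eff)
  sp <- fid_to_spectrum(fid, acq$bandwidth_hz, acq$ref_freq_mhz)$spectrum
  wf <- fit_water(sp, wb)
  expect_equal(wf$amplitude, amp, tolerance = 1e-6)
  expect_equal(wf$shift_hz, 1.5, tolerance = 1e-3)
  expect_false(wf$flagged)

  # pure-CSF / pure-GM amplitude ratio equals the compartment model
  relax <- default_relaxation_table()
  wt <- relax$water
  a_gm <- 1000 * wt$conc_gm * ernst_factor(27, 200, wt$t1_gm_ms)
  a_csf <- 1000 * wt$conc_csf * ernst_factor(27, 200, wt$t1_csf_ms)
  f_gm <- fit_water(fid_to_spectrum(a_gm * wb$signals[, 1], acq$bandwidth_hz,
                                    acq$ref_freq_mhz)$spectrum, wb)
  f_csf <- fit_water(fid_to_spectrum(a_csf * wb$signals[, 1], acq$bandwidth_hz,
                                     acq$ref_freq_mhz)$spectrum, wb)
  expect_equal(f_csf$amplitude / f_gm$amplitude,
               (53.8 * ernst_factor(27, 200, wt$t1_csf_ms)) /
                 (36.1 * ernst_factor(27, 200, wt$t1_gm_ms)),
               tolerance = 1e-6)

  # zero signal: flagged, no downstream zero-divide
  wf0 <- fit_water(complex(real = rep(0, wb$n_points)), wb, noise_sd = 0.1)
  expect_true(wf0$flagged)
})
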