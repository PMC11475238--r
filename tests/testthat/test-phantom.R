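test_that("phantom fractions are a valid partition and ROIs make sense", {
  ph <- build_phantom(c(32, 32, 16))
  s <- ph$f_gm + ph$f_wm + ph$f_csf + ph$f_bg
  expect_equal(range(s), c(1, 1), tolerance = 1e-12)
  for (m in list(ph$f_gm, ph$f_wm, ph$f_csf, ph$f_bg)) {
    expect_true(all(m >= 0 & m <= 1))
  }
  # every named ROI is populated
  expect_true(all(seq_along(ph$roi_names) %in% unique(ph$roi_labels)))
  # deep WM ROI is WM-dominant
  wm_roi <- ph$roi_labels == which(ph$roi_names == "deep WM")
  expect_gt(mean(ph$f_wm[wm_roi]), mean(ph$f_gm[wm_roi]))
  # scalp and brain are disjoint
  expect_false(any(ph$brain_mask & ph$scalp_mask))
  # determinism of the geometry
  ph2 <- build_phantom(c(32, 32, 16))
  expect_identical(ph$f_gm, ph2$f_gm)
  expect_identical(ph$roi_labels, ph2$roi_labels)

  expect_error(build_phantom(c(8, 8, 4)), "at least")
  bad_spec <- list(list(name = "nowhere", tissue = "GM", y_min = 0.99))
  expect_error(build_phantom(c(16, 16, 8), roi_spec = bad_spec), "zero voxels")
})

test_that("ground-truth draws have the requested inter-subject structure", {
  ph <- build_phantom(c(16, 16, 8))

  # cv = 0: all subjects identical
  p0 <- assign_truth_concentrations(ph, inter_subject_cv = 0,
                                    n_subjects = 3, seed = 5)
  expect_equal(p0$truth$subject_tissue_mM[1, , ],
               p0$truth$subject_tissue_mM[3, , ])

  # empirical CV of 200 subjects at 10% within the sampling-error bound
  p <- assign_truth_concentrations(ph, inter_subject_cv = 10,
                                   n_subjects = 200, seed = 6)
  draws <- p$truth$subject_tissue_mM[, "NAA", "GM"]
  expect_gt(100 * sd(draws) / mean(draws), 8.5)
  expect_lt(100 * sd(draws) / mean(draws), 11.5)
  # mean-parameterised: sample mean near the tissue mean
  expect_equal(mean(draws), 10.0, tolerance = 0.03 * 10)

  # pure-CSF voxel carries no metabolites (model definition)
  pcsf <- p
  v <- which.max(p$f_csf)
  pcsf$f_gm[v] <- 0; pcsf$f_wm[v] <- 0; pcsf$f_csf[v] <- 1; pcsf$f_bg[v] <- 0
  maps <- truth_concentration_maps(pcsf, 1)
  expect_identical(unname(vapply(maps, function(mm) mm[v], numeric(1))),
                   rep(0, length(maps)))

  expect_error(assign_truth_concentrations(ph, n_subjects = 1), ">= 2")
  tm <- default_tissue_means(); tm$gm_mM[1] <- -1
  expect_error(assign_truth_concentrations(ph, tissue_means = tm),
               "non-negative")
})

test_that("synthesised scans follow the forward model and are reproducible", {
  ph <- small_phantom()
  basis <- full_basis()
  wb <- build_water_basis()

  ds <- synthesize_subject(ph, 1, basis, wb, noise_sd = 0,
                           lipid_amplitude = 0, seed = 4)
  # water-scan amplitude in any voxel equals the compartment model
  wsp <- subject_spectra(ds, "water")
  relax <- default_relaxation_table()
  wt <- relax$water
  idx <- which(ph$f_gm[ds$voxel_index] > 0.8)[1]
  v <- ds$voxel_index[idx]
  wf <- fit_water(wsp$spectra[, idx], wb)
  expected <- 1000 * (ph$f_gm[v] * wt$conc_gm *
                        ernst_factor(27, 200, wt$t1_gm_ms) +
                      ph$f_wm[v] * wt$conc_wm *
                        ernst_factor(27, 200, wt$t1_wm_ms) +
                      ph$f_csf[v] * wt$conc_csf *
                        ernst_factor(27, 200, wt$t1_csf_ms))
  expect_equal(wf$amplitude, expected, tolerance = 1e-6)

  # reproducibility: same seed gives bit-identical FIDs
  ds1 <- synthesize_subject(ph, 2, basis, wb, seed = 9)
  ds2 <- synthesize_subject(ph, 2, basis, wb, seed = 9)
  expect_identical(ds1$metabolite_fids, ds2$metabolite_fids)
  expect_identical(ds1$water_fids, ds2$water_fids)

  expect_error(synthesize_subject(ph, 1, basis, wb, noise_sd = -1), ">= 0")
})

test_that("scalp lipid bleeds into peripheral but not central brain voxels", {
  ph <- small_phantom()
  basis <- full_basis()
  wb <- build_water_basis()
  ds <- synthesize_subject(ph, 1, basis, wb, noise_sd = 0,
                           lipid_amplitude = 30, seed = 4)
  sp <- subject_spectra(ds)
  r <- ph$coords$r[ds$voxel_index]
  brain <- ph$brain_mask[ds$voxel_index]
  peri <- brain & r > 0.8
  centre <- brain & r < 0.4
  e_peri <- mean(band_energy(sp$spectra[, peri], sp$ppm))
  e_centre <- mean(band_energy(sp$spectra[, centre], sp$ppm))
  expect_gt(e_peri, 5 * e_centre)
})

test_that("Hamming smoothing conserves mass away from edges", {
  arr <- array(0, c(16, 16, 8)); arr[8, 8, 4] <- 1
  sm <- smooth3d_hamming(arr, 5)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_equal(dim(sm), dim(arr))
  expect_gt(sm[8, 8, 4], sm[8, 8, 3])
  const <- array(2, c(16, 16, 8))
  smc <- smooth3d_hamming(const, 5)
  # interior unchanged for a constant field
  expect_equal(smc[6:10, 6:10, 3:6], const[6:10, 6:10, 3:6],
               tolerance = 1e-12)
})
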