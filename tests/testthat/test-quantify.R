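test_that("Ernst factor has the right limits and printed constants", {
  # fully relaxed limit
  expect_equal(ernst_factor(39, 1e7, 1500), sin(39 * pi / 180),
               tolerance = 1e-6)
  # closed-form E1 for the tCr GM T1 at the metabolite-scan TR
  expect_equal(exp(-450 / 1780), 0.7766, tolerance = 1e-4)
  # the water-scan flip angle: argmax over theta for TR 200 ms and the
  # GM/WM mean water T1 (1775 ms), via a grid-search oracle
  grid <- seq(1, 90, by = 0.01)
  best <- grid[which.max(ernst_factor(grid, 200, 1775))]
  expect_equal(best, ernst_angle(200, 1775), tolerance = 0.01)
  expect_equal(round(ernst_angle(200, 1775)), 27)
  expect_error(ernst_factor(39, 450, -1), "t1")
})

test_that("voxel water content mixes compartments linearly", {
  w <- voxel_water_concentration(c(1, 0, 0))
  expect_equal(w$water_mol_per_l, 36.1)
  expect_equal(voxel_water_concentration(c(0, 0, 1))$water_mol_per_l, 53.8)
  expect_equal(voxel_water_concentration(c(0.5, 0.5, 0))$water_mol_per_l,
               39.7)
  expect_true(voxel_water_concentration(c(0, 0, 0))$flagged)
  # effective Ernst factor is a weighted average of compartment factors
  wt <- default_relaxation_table()$water
  e_gm <- ernst_factor(27, 200, wt$t1_gm_ms)
  e_csf <- ernst_factor(27, 200, wt$t1_csf_ms)
  wmix <- voxel_water_concentration(c(0.5, 0, 0.5))
  expect_equal(wmix$ernst_eff,
               (0.5 * 36.1 * e_gm + 0.5 * 53.8 * e_csf) /
                 (0.5 * 36.1 + 0.5 * 53.8))
})

test_that("concentration estimation inverts the forward model", {
  expect_equal(estimate_concentration(0, 100, c(1, 0, 0), "NAA"), 0)

  # symmetric cancellation: equal T1 everywhere, identical scans
  relax_flat <- default_relaxation_table()
  relax_flat$metabolite_t1$t1_gm_ms[] <- 1500
  relax_flat$metabolite_t1$t1_wm_ms[] <- 1500
  relax_flat$water$t1_gm_ms <- 1500
  relax_flat$water$t1_wm_ms <- 1500
  relax_flat$water$t1_csf_ms <- 1500
  acq <- metabolite_acquisition()
  c_est <- estimate_concentration(2, 100, c(1, 0, 0), "NAA", relax_flat,
                                  met_acq = acq, water_acq = acq)
  expect_equal(c_est, (2 / 100) * 36.1 * 1000)

  # full forward model: synthesise amplitudes, invert, recover the truth
  relax <- default_relaxation_table()
  met_acq <- metabolite_acquisition(); wat_acq <- water_acquisition()
  wt <- relax$water
  for (f in list(c(1, 0, 0), c(0.3, 0.6, 0.1), c(0.2, 0.3, 0.5))) {
    truth_tissue <- 10                       # mM per tissue volume
    truth_voxel <- truth_tissue * (f[1] + f[2])
    t1 <- relax$metabolite_t1[relax$metabolite_t1$compound == "NAA", ]
    e_m <- (f[1] * ernst_factor(39, 450, t1$t1_gm_ms) +
              f[2] * ernst_factor(39, 450, t1$t1_wm_ms)) / (f[1] + f[2])
    a_m <- truth_voxel * e_m
    a_w <- 1000 * (f[1] * wt$conc_gm * ernst_factor(27, 200, wt$t1_gm_ms) +
                     f[2] * wt$conc_wm * ernst_factor(27, 200, wt$t1_wm_ms) +
                     f[3] * wt$conc_csf * ernst_factor(27, 200, wt$t1_csf_ms))
    est <- estimate_concentration(a_m, a_w, f, "NAA", relax, met_acq, wat_acq)
    expect_equal(est, truth_tissue, tolerance = 1e-9)
  }

  # receiver-gain invariance and monotonicity
  f <- c(0.4, 0.5, 0.1)
  base <- estimate_concentration(3, 200, f, "Glu")
  expect_equal(estimate_concentration(3 * 7.3, 200 * 7.3, f, "Glu"), base,
               tolerance = 1e-12)
  expect_gt(estimate_concentration(4, 200, f, "Glu"), base)
  expect_lt(estimate_concentration(3, 250, f, "Glu"), base)

  flagged <- estimate_concentration(1, 100, c(0, 0, 1), "NAA")
  expect_true(is.na(flagged))
  expect_error(estimate_concentration(1, 100, c(1, 0, 0), "Unobtainium"),
               "Unobtainium")
})

test_that("MAD filter excludes gross outliers only", {
  expect_false(any(mad_outlier_filter(rep(5, 10))))

  # brute-force enumerated case: 1..10 plus 1000
  v <- c(1:10, 1000)
  excl <- mad_outlier_filter(v, k = 13)
  med <- median(v); mad_raw <- median(abs(v - med))
  brute <- abs(v - med) > 13 * mad_raw
  expect_identical(excl, brute)
  expect_identical(which(excl), 11L)

  # degenerate spread with an outlier: relative-tolerance fallback
  vd <- c(rep(3, 9), 300)
  expect_message(ex <- mad_outlier_filter(vd), "MAD = 0")
  expect_identical(which(ex), 10L)

  expect_error(mad_outlier_filter(c(1, 2)), "at least 5")
})

test_that("quality mask applies all four rules with correct counts", {
  set.seed(77)
  nv <- 400
  mk <- function() matrix(rexp(nv * 2, 1 / 15), nv, 2,
                          dimnames = list(NULL, c("NAA", "tCr")))
  maps <- list(snr = runif(nv, 2, 25), fwhm_ppm = runif(nv, 0.02, 0.2),
               crlb = mk(), amplitude = matrix(rnorm(nv * 2, 10, 1), nv, 2,
                 dimnames = list(NULL, c("NAA", "tCr"))))
  maps$amplitude[7, "NAA"] <- 500            # MAD outlier
  qm <- build_quality_mask(maps)

  # brute-force recount per rule
  expect_equal(qm$counts$snr, sum(maps$snr < 5))
  expect_equal(qm$counts$fwhm, sum(maps$fwhm_ppm > 0.15))
  for (cm in c("NAA", "tCr")) {
    expect_equal(unname(qm$counts$crlb[cm]), sum(maps$crlb[, cm] > 40))
    mad_ex <- mad_outlier_filter(maps$amplitude[, cm])
    expect_equal(unname(qm$counts$mad[cm]), sum(mad_ex))
    brute <- maps$snr >= 5 & maps$fwhm_ppm <= 0.15 &
      maps$crlb[, cm] <= 40 & !mad_ex
    expect_identical(unname(qm$pass[, cm]), brute)
  }

  # boundary behaviour: SNR 4.9 excluded, a fully clean voxel included
  maps2 <- maps
  maps2$snr[1] <- 4.9; maps2$fwhm_ppm[1] <- 0.05
  maps2$crlb[1, ] <- 10
  qm2 <- build_quality_mask(maps2)
  expect_false(qm2$pass[1, "NAA"])
  clean <- which(maps$snr >= 5 & maps$fwhm_ppm <= 0.15 &
                   maps$crlb[, "NAA"] <= 40)[1]
  expect_true(qm$pass[clean, "NAA"])

  expect_error(build_quality_mask(maps[c("snr", "crlb", "amplitude")]),
               "fwhm")
})
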