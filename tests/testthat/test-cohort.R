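test_that("ROI pass fractions count jointly passing voxels", {
  nv <- 200
  crlb <- matrix(10, nv, 4,
                 dimnames = list(NULL, c("NAA", "tCr", "tCho", "mIns")))
  roi <- rep(c(TRUE, FALSE), each = nv / 2)
  expect_equal(roi_pass_fraction(crlb, roi), 100)

  crlb2 <- crlb
  crlb2[seq(1, nv / 2, by = 2), "mIns"] <- 50   # half the ROI voxels fail
  expect_equal(roi_pass_fraction(crlb2, roi), 50)

  set.seed(12)
  crlb3 <- matrix(rexp(nv * 4, 1 / 30), nv, 4,
                  dimnames = list(NULL, c("NAA", "tCr", "tCho", "mIns")))
  brute <- 100 * sum(apply(crlb3[roi, ] < 40, 1, all)) / sum(roi)
  expect_equal(roi_pass_fraction(crlb3, roi), brute)

  expect_error(roi_pass_fraction(crlb, rep(FALSE, nv)), "empty")
})

test_that("ROI classification matches the printed rules and is monotone", {
  expect_identical(classify_roi(85), "good")
  expect_identical(classify_roi(80), "good")
  expect_identical(classify_roi(70), "acceptable")
  expect_identical(classify_roi(66), "acceptable")
  expect_identical(classify_roi(50), "rejected")
  ranks <- c(rejected = 1, acceptable = 2, good = 3)
  cls <- ranks[classify_roi(seq(0, 100, by = 1))]
  expect_true(all(diff(cls) >= 0))
})

test_that("metabolite qualification applies both voxel rules", {
  roi_pass <- cbind(good_met = c(90, 80, 80), mid_met = c(66, 66, 66),
                    absent = c(0, 0, 0))
  brain_fit <- c(good_met = 95, mid_met = 80, absent = 0)
  q <- metabolite_qualification(roi_pass, brain_fit)
  expect_true(q$qualified[q$metabolite == "good_met"])
  # boundary: mean pass exactly 66 is not qualified (strict >)
  expect_false(q$qualified[q$metabolite == "mid_met"])
  # never fit anywhere: discarded by the brain-level 10% rule
  expect_true(q$discarded[q$metabolite == "absent"])
  expect_false(q$qualified[q$metabolite == "absent"])
})

test_that("ROI means, ratios and CVs match hand calculations", {
  conc <- c(rep(10, 6), rep(NA, 2))
  keep <- rep(TRUE, 8); roi <- c(rep(TRUE, 6), TRUE, FALSE)
  rm_ <- roi_mean_concentration(conc, keep, roi)
  expect_equal(rm_$mean, 10); expect_equal(rm_$sd, 0); expect_equal(rm_$n, 6L)

  half <- roi_mean_concentration(c(rep(8, 5), rep(12, 5)), rep(TRUE, 10),
                                 rep(TRUE, 10))
  expect_equal(half$mean, 10)

  set.seed(3)
  v <- rnorm(50, 7, 1); qmask <- runif(50) > 0.3; rmask <- runif(50) > 0.5
  got <- roi_mean_concentration(v, qmask, rmask)
  expect_equal(got$mean, mean(v[qmask & rmask]), tolerance = 1e-12)

  expect_true(roi_mean_concentration(v, rep(FALSE, 50), rmask)$flagged)

  # ratios
  same <- ratio_to_tcr(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$ratios, rep(1, 3))
  expect_equal(ratio_to_tcr(c(0.30 * 8, 0.40 * 10), c(8, 10))$mean, 0.35)
  expect_true(ratio_to_tcr(c(1, 2), c(0, 2))$flagged)

  # CVs
  expect_equal(inter_subject_cv(c(10, 10, 10)), 0)
  expect_equal(inter_subject_cv(c(8, 10, 12)), 20)
  expect_error(inter_subject_cv(7), "at least 2")
  # scale invariance
  set.seed(8); x <- rlnorm(30, 2, 0.1)
  expect_equal(inter_subject_cv(x), inter_subject_cv(137 * x),
               tolerance = 1e-12)
})

test_that("truth-level cohort CV recovery stays within the sampling bound", {
  ph <- build_phantom(c(16, 16, 8))
  ph <- assign_truth_concentrations(ph, inter_subject_cv = 10,
                                    n_subjects = 20, seed = 41)
  roi <- ph$roi_labels == which(ph$roi_names == "deep WM")
  means <- vapply(1:20, function(s) {
    mean(truth_concentration_maps(ph, s, "tissue")$tCr[roi])
  }, numeric(1))
  cv <- inter_subject_cv(means)
  expect_gt(cv, 5); expect_lt(cv, 15)
})

test_that("column summaries and nearest-neighbour resampling behave", {
  expect_identical(summarize_column(5.5), c(mean = 5.5, min = 5.5, max = 5.5))
  expect_identical(summarize_column(c(8, 10, 12), digits = 0),
                   c(mean = 10, min = 8, max = 12))

  arr <- array(seq_len(4 * 4 * 2), c(4, 4, 2))
  expect_identical(resample_map_to_labels(arr, c(4, 4, 2)), arr)
  const <- array(3, c(4, 4, 2))
  up <- resample_map_to_labels(const, c(8, 8, 4))
  expect_true(all(up == 3)); expect_equal(dim(up), c(8L, 8L, 4L))
  up2 <- resample_map_to_labels(arr, c(8, 8, 4))
  expect_setequal(unique(as.vector(up2)), unique(as.vector(arr)))
  expect_error(resample_map_to_labels(arr, c(0, 4, 2)), "overlap")
})

test_that("cohort statistics honour exclusions and recompute brute force", {
  set.seed(9)
  rm_arr <- array(rlnorm(6 * 3 * 2, 2, 0.1), c(6, 3, 2),
                  dimnames = list(NULL, c("r1", "r2", "r3"), c("NAA", "tCr")))
  stats <- cohort_statistics(rm_arr)
  row <- stats$concentration[stats$concentration$roi == "r2" &
                               stats$concentration$metabolite == "NAA", ]
  expect_equal(row$mean, mean(rm_arr[, "r2", "NAA"]))
  expect_equal(row$cv_percent, inter_subject_cv(rm_arr[, "r2", "NAA"]))
  rrow <- stats$ratio[stats$ratio$roi == "r1", ]
  expect_equal(rrow$mean, mean(rm_arr[, "r1", "NAA"] / rm_arr[, "r1", "tCr"]))

  excl <- data.frame(subject = c(1L, 2L), roi = c(NA, "r3"))
  st2 <- cohort_statistics(rm_arr, excl)
  row2 <- st2$concentration[st2$concentration$roi == "r3" &
                              st2$concentration$metabolite == "tCr", ]
  expect_equal(row2$mean, mean(rm_arr[3:6, "r3", "tCr"]))
  expect_equal(unname(st2$n_subjects_used["r3"]), 4)
})
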