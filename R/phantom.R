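#' Build a synthetic head phantom with tissue fractions and ROI labels
#'
#' Constructs a 3D ellipsoidal "head" on a voxel grid with smooth per-voxel
#' gray-matter / white-matter / CSF fractions: a WM core, a cortical GM
#' shell, a CSF rim plus central ventricles, and an outer scalp ring that
#' carries subcutaneous lipid but no brain tissue. At every voxel
#' f_GM + f_WM + f_CSF + f_background = 1, each in [0, 1]. ROI labels are
#' assigned from a declarative specification (tissue dominance crossed with
#' spatial sectors); ROIs are disjoint and each must contain at least one
#' voxel.
#'
#' @param grid_shape integer vector of 3 voxel dimensions (min 16 x 16 x 8).
#' @param voxel_mm isotropic nominal voxel size in mm.
#' @param roi_spec list of ROI definitions, see [default_roi_spec()].
#' @param seed integer seed stored with the phantom; the geometry itself is
#'   deterministic.
#' @return An object of class `phantom_cohort` (scaffold: no concentrations
#'   yet) with fraction maps, masks and ROI labels.
#' @export
build_phantom <- function(grid_shape = c(32, 32, 16), voxel_mm = 3.4,
                          roi_spec = default_roi_spec(), seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3)
  if (grid_shape[1] < 16 || grid_shape[2] < 16 || grid_shape[3] < 8)
    stop("grid must be at least 16 x 16 x 8")
  if (length(roi_spec) == 0) stop("roi_spec is empty")

  d <- grid_shape
  # normalised coordinates in [-1, 1] per axis (voxel centres)
  nx <- array(rep((seq_len(d[1]) - 0.5) / d[1] * 2 - 1, times = d[2] * d[3]), d)
  ny <- array(rep(rep((seq_len(d[2]) - 0.5) / d[2] * 2 - 1, each = d[1]),
                  times = d[3]), d)
  nz <- array(rep((seq_len(d[3]) - 0.5) / d[3] * 2 - 1, each = d[1] * d[2]), d)
  # ellipsoidal head radius (slightly prolate in y)
  r <- sqrt((nx / 0.92)^2 + (ny / 0.98)^2 + (nz / 0.90)^2)

  scalp_mask <- r > 0.93 & r <= 1.04
  inside <- r <= 0.93

  # smooth tissue weights on the head radius
  w_wm <- 1 / (1 + exp((r - 0.60) / 0.06))
  w_gm <- exp(-((r - 0.78) / 0.10)^2)
  w_csf_rim <- exp(-((r - 0.91) / 0.045)^2)
  # ventricles: small central CSF pockets, one per hemisphere
  rv1 <- sqrt(((nx - 0.16) / 0.14)^2 + (ny / 0.35)^2 + (nz / 0.22)^2)
  rv2 <- sqrt(((nx + 0.16) / 0.14)^2 + (ny / 0.35)^2 + (nz / 0.22)^2)
  w_vent <- 6 / (1 + exp((pmin(rv1, rv2) - 1) / 0.10))
  w_csf <- w_csf_rim + w_vent

  tot <- w_wm + w_gm + w_csf
  f_gm <- ifelse(inside, w_gm / tot, 0)
  f_wm <- ifelse(inside, w_wm / tot, 0)
  f_csf <- ifelse(inside, w_csf / tot, 0)
  f_bg <- pmin(pmax(1 - f_gm - f_wm - f_csf, 0), 1)

  brain_mask <- inside
  labels <- array(0L, d)
  roi_names <- vapply(roi_spec, `[[`, character(1), "name")
  if (anyDuplicated(roi_names)) stop("duplicate ROI names")
  for (i in seq_along(roi_spec)) {
    sel <- roi_voxels(roi_spec[[i]], f_gm, f_wm, f_csf, nx, ny, nz, r,
                      brain_mask) & labels == 0L
    if (!any(sel)) stop("ROI '", roi_spec[[i]]$name, "' has zero voxels")
    labels[sel] <- i
  }

  structure(list(
    grid_shape = d, voxel_mm = voxel_mm,
    f_gm = f_gm, f_wm = f_wm, f_csf = f_csf, f_bg = f_bg,
    brain_mask = brain_mask, scalp_mask = scalp_mask,
    roi_labels = labels, roi_names = roi_names,
    coords = list(nx = nx, ny = ny, nz = nz, r = r),
    seed = as.integer(seed)
  ), class = "phantom_cohort")
}

roi_voxels <- function(spec, f_gm, f_wm, f_csf, nx, ny, nz, r, brain_mask) {
  sel <- brain_mask & f_csf < 0.3
  sel <- sel & switch(spec$tissue,
    GM = f_gm >= 0.5,
    WM = f_wm >= 0.5,
    mixed = f_gm >= 0.2 & f_wm >= 0.2,
    stop("unknown tissue class: ", spec$tissue))
  if (!is.null(spec$r_max)) sel <- sel & r < spec$r_max
  if (!is.null(spec$r_min)) sel <- sel & r >= spec$r_min
  if (!is.null(spec$y_min)) sel <- sel & ny > spec$y_min
  if (!is.null(spec$y_max)) sel <- sel & ny < spec$y_max
  if (!is.null(spec$x_min)) sel <- sel & nx > spec$x_min
  if (!is.null(spec$x_max)) sel <- sel & nx < spec$x_max
  sel
}

#' Default ROI specification
#'
#' Six regions covering the tissue classes the ROI analysis distinguishes:
#' a deep WM core, left and right peripheral WM, anterior ("frontal") and
#' posterior ("occipital") cortical GM, and a mixed GM+WM cortex band.
#' @return List of ROI definitions for [build_phantom()].
#' @export
default_roi_spec <- function() {
  list(
    list(name = "deep WM",      tissue = "WM", r_max = 0.45),
    list(name = "left WM",      tissue = "WM", r_min = 0.45, x_max = -0.05),
    list(name = "right WM",     tissue = "WM", r_min = 0.45, x_min = 0.05),
    list(name = "frontal GM",   tissue = "GM", y_min = 0.15),
    list(name = "occipital GM", tissue = "GM", y_max = -0.15),
    list(name = "mixed cortex", tissue = "mixed", y_min = -0.15, y_max = 0.15)
  )
}

#' Default GM/WM tissue concentration means (mM)
#'
#' Approximate tissue-level means for the simulated compounds, chosen to
#' reproduce the concentration ranges and GM/WM contrasts typical of healthy
#' adult brain at 7 T (glutamate higher in GM, choline higher in WM). The MM
#' row is the macromolecular background amplitude expressed on the same
#' scale.
#' @return data.frame with columns `compound`, `gm_mM`, `wm_mM`.
#' @export
default_tissue_means <- function() {
  data.frame(
    compound = c("NAA", "tCr", "tCho", "Glu", "Gln", "mIns", "NAAG", "MM"),
    gm_mM = c(10.0, 8.0, 1.7, 9.0, 3.0, 5.3, 1.0, 4.0),
    wm_mM = c(9.7, 7.2, 2.0, 7.0, 2.0, 5.2, 2.0, 4.0)
  )
}

#' Draw per-subject ground-truth concentrations
#'
#' Subject-level tissue concentrations are drawn log-normally and
#' independently per compound and tissue class around the given means, with
#' the requested inter-subject coefficient of variation; the log-normal is
#' mean-parameterised so that the expected value equals the tissue mean and
#' the CV equals `inter_subject_cv`. The voxel-level ground truth is
#' `f_GM * C_GM,s + f_WM * C_WM,s`; CSF carries water but no metabolites.
#'
#' @param phantom a `phantom_cohort` scaffold from [build_phantom()].
#' @param tissue_means data.frame as [default_tissue_means()].
#' @param inter_subject_cv inter-subject CV in percent (>= 0).
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer seed for the draws.
#' @return The phantom with `truth` attached: a list with the subject-level
#'   concentration array (`n_subjects x n_compounds x 2`), compound names
#'   and the generation parameters.
#' @export
assign_truth_concentrations <- function(phantom, tissue_means =
                                          default_tissue_means(),
                                        inter_subject_cv = 10,
                                        n_subjects = 5, seed = 1L) {
  stopifnot(inherits(phantom, "phantom_cohort"))
  if (inter_subject_cv < 0) stop("inter_subject_cv must be >= 0")
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (any(tissue_means$gm_mM < 0) || any(tissue_means$wm_mM < 0))
    stop("tissue means must be non-negative")
  cv <- inter_subject_cv / 100
  sigma <- sqrt(log1p(cv^2))
  m <- nrow(tissue_means)
  conc <- array(NA_real_, c(n_subjects, m, 2),
                dimnames = list(NULL, tissue_means$compound, c("GM", "WM")))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (s in seq_len(n_subjects)) {
    z <- matrix(stats::rnorm(2 * m), m, 2)
    conc[s, , 1] <- tissue_means$gm_mM * exp(sigma * z[, 1] - sigma^2 / 2)
    conc[s, , 2] <- tissue_means$wm_mM * exp(sigma * z[, 2] - sigma^2 / 2)
  }
  phantom$truth <- list(
    subject_tissue_mM = conc,
    compounds = tissue_means$compound,
    tissue_means = tissue_means,
    inter_subject_cv = inter_subject_cv,
    n_subjects = as.integer(n_subjects),
    seed = as.integer(seed),
    subject_flags = rep("ok", n_subjects)
  )
  phantom
}

#' Ground-truth concentration maps for one subject
#'
#' @param phantom a `phantom_cohort` with truth attached.
#' @param subject subject index.
#' @param reference `"voxel"` gives concentration per voxel volume
#'   (`f_GM*C_GM + f_WM*C_WM`); `"tissue"` divides by the tissue fraction
#'   `f_GM + f_WM` (the quantity the tissue-corrected pipeline estimates).
#' @return Named list of 3D arrays, one per compound.
#' @export
truth_concentration_maps <- function(phantom, subject,
                                     reference = c("voxel", "tissue")) {
  reference <- match.arg(reference)
  tr <- phantom$truth
  if (is.null(tr)) stop("phantom has no truth; call assign_truth_concentrations()")
  denom <- if (reference == "tissue") {
    dn <- phantom$f_gm + phantom$f_wm
    dn[dn <= 0] <- NA_real_
    dn
  } else 1
  maps <- lapply(seq_along(tr$compounds), function(m) {
    (phantom$f_gm * tr$subject_tissue_mM[subject, m, 1] +
       phantom$f_wm * tr$subject_tissue_mM[subject, m, 2]) / denom
  })
  names(maps) <- tr$compounds
  maps
}

#' Flag a subject as motion-corrupted
#'
#' Motion-flagged subjects are synthesised with broadened lines (extra
#' damping) and spatial zero-order phase ramps, which drives voxels past the
#' linewidth quality threshold.
#' @param phantom a `phantom_cohort` with truth attached.
#' @param subject subject index.
#' @return The phantom with the flag set.
#' @export
flag_motion_subject <- function(phantom, subject) {
  if (is.null(phantom$truth)) stop("phantom has no truth")
  phantom$truth$subject_flags[subject] <- "motion"
  phantom
}

#' Separable 3D Hamming smoothing
#'
#' Convolves a 3D array with a normalised Hamming window along each axis
#' (zero padding at the edges). Used as the point-spread model for the
#' k-space apodisation of the acquisition and for the spatial bleed of the
#' scalp lipid signal into peripheral brain voxels.
#'
#' @param arr 3D numeric array.
#' @param width odd window length in voxels.
#' @return Smoothed array of the same shape.
#' @export
smooth3d_hamming <- function(arr, width = 5) {
  stopifnot(length(dim(arr)) == 3, width %% 2 == 1)
  if (width == 1) return(arr)
  k <- 0.54 - 0.46 * cos(2 * pi * (0:(width - 1)) / (width - 1))
  k <- k / sum(k)
  half <- (width - 1) / 2
  conv_axis <- function(a, axis) {
    d <- dim(a)
    out <- array(0, d)
    for (j in seq_len(width)) {
      off <- j - 1 - half
      src <- seq_len(d[axis]) + off
      ok <- src >= 1 & src <= d[axis]
      idx_to <- which(ok); idx_from <- src[ok]
      if (axis == 1) out[idx_to, , ] <- out[idx_to, , ] + k[j] * a[idx_from, , ]
      if (axis == 2) out[, idx_to, ] <- out[, idx_to, ] + k[j] * a[, idx_from, ]
      if (axis == 3) out[, , idx_to] <- out[, , idx_to] + k[j] * a[, , idx_from]
    }
    out
  }
  conv_axis(conv_axis(conv_axis(arr, 1), 2), 3)
}

#' Calibrate the generator noise level to a target tCr SNR
#'
#' Computes the phased tCr peak height of the modelled spectrum in a
#' representative deep-WM voxel and returns the complex-noise standard
#' deviation that yields the requested spectral SNR there.
#'
#' @param phantom phantom with truth attached.
#' @param subject subject index used for the representative amplitudes.
#' @param basis metabolite `basis_set`.
#' @param relax relaxation table, see [default_relaxation_table()].
#' @param acq metabolite-scan acquisition.
#' @param target_snr target tCr SNR (dimensionless).
#' @param extra_damping_hz line-broadening applied by the generator, Hz.
#' @return Noise standard deviation per real/imaginary component.
#' @export
calibrate_noise_sd <- function(phantom, subject, basis,
                               relax = default_relaxation_table(),
                               acq = metabolite_acquisition(),
                               target_snr = 11, extra_damping_hz = 12) {
  vx <- which.max(phantom$f_wm)
  amps <- voxel_model_amplitudes(phantom, subject, vx, relax, acq)
  fid <- basis$signals %*% amps[basis$compound_names]
  fid <- fid * damping_vector(acq, extra_damping_hz)
  sp <- fid_to_spectrum(as.vector(fid), acq$bandwidth_hz, acq$ref_freq_mhz,
                        acq$carrier_ppm)
  tcr_fid <- basis$signals[, "tCr"] * amps["tCr"] *
    damping_vector(acq, extra_damping_hz)
  tcr_sp <- fid_to_spectrum(as.vector(tcr_fid), acq$bandwidth_hz,
                            acq$ref_freq_mhz, acq$carrier_ppm)
  near <- abs(tcr_sp$ppm - 3.027) < 0.1
  peak <- max(Re(tcr_sp$spectrum[near] *
                   exp(-1i * Arg(tcr_sp$spectrum[near][
                     which.max(Mod(tcr_sp$spectrum[near]))]))))
  peak / target_snr
}

# steady-state model amplitude (signal units = mM x Ernst factor) of every
# basis compound at one voxel
voxel_model_amplitudes <- function(phantom, subject, voxel, relax, acq) {
  tr <- phantom$truth
  fg <- phantom$f_gm[voxel]; fw <- phantom$f_wm[voxel]
  amps <- vapply(seq_along(tr$compounds), function(m) {
    cm <- tr$compounds[m]
    truth <- fg * tr$subject_tissue_mM[subject, m, 1] +
      fw * tr$subject_tissue_mM[subject, m, 2]
    truth * metabolite_ernst_eff(fg, fw, cm, relax, acq)
  }, numeric(1))
  names(amps) <- tr$compounds
  amps
}

# tissue-fraction-weighted Ernst factor of a metabolite over GM/WM
metabolite_ernst_eff <- function(f_gm, f_wm, compound, relax, acq) {
  ft <- f_gm + f_wm
  if (ft <= 0) return(0)
  t1 <- relax$metabolite_t1[relax$metabolite_t1$compound == compound, ]
  if (nrow(t1) == 0) stop("no T1 entry for compound: ", compound)
  (f_gm * ernst_factor(acq$flip_deg, acq$tr_ms, t1$t1_gm_ms) +
     f_wm * ernst_factor(acq$flip_deg, acq$tr_ms, t1$t1_wm_ms)) / ft
}

# time-domain modulation for extra Lorentzian broadening (FWHM in Hz) and
# frequency shift (Hz), on the acquisition's (t + delay) axis
damping_vector <- function(acq, extra_damping_hz, shift_hz = 0) {
  t_eff <- (seq_len(acq$n_points) - 1) / acq$bandwidth_hz + acq$delay_s
  exp((2i * pi * shift_hz - pi * extra_damping_hz) * t_eff)
}

#' Synthesise the two MRSI scans of one subject
#'
#' For every brain voxel the metabolite-scan FID is the amplitude-weighted
#' sum of the basis compounds (amplitude = voxel ground truth times the
#' tissue-weighted Ernst saturation factor at TR 450 ms / 39 deg), broadened
#' by an extra Lorentzian damping, plus a scalp-lipid term that bleeds into
#' peripheral brain voxels through the Hamming point spread, plus complex
#' Gaussian noise. The water-reference FID is the water basis signal scaled
#' by the compartment water content (36.1 / 43.3 / 53.8 mol/L for GM, WM and
#' CSF) times the compartment Ernst factors at TR 200 ms / 27 deg.
#' Motion-flagged subjects get additional line broadening and a spatial
#' zero-order phase ramp. Noise-only prescan FIDs are stored for the
#' pseudo-replica noise estimator.
#'
#' @param phantom phantom with truth attached.
#' @param subject subject index.
#' @param basis metabolite `basis_set` (metabolite-scan acquisition).
#' @param water_basis single-compound `basis_set` for water
#'   (water-scan acquisition), e.g. from [build_water_basis()].
#' @param relax relaxation table.
#' @param noise_sd complex-noise SD per component; `NULL` calibrates it to
#'   `target_snr` via [calibrate_noise_sd()].
#' @param target_snr tCr SNR used when `noise_sd` is `NULL`.
#' @param lipid_amplitude scalp lipid amplitude in generator signal units.
#' @param extra_damping_hz extra linewidth applied to all voxels, Hz.
#' @param seed integer seed for the noise streams.
#' @param n_prescans number of stored noise-only prescan FIDs.
#' @return An object of class `subject_dataset` holding complex FID matrices
#'   (points x voxels) for both scans over the brain+scalp voxel set.
#' @export
synthesize_subject <- function(phantom, subject, basis, water_basis,
                               relax = default_relaxation_table(),
                               noise_sd = NULL, target_snr = 11,
                               lipid_amplitude = 30, extra_damping_hz = 12,
                               seed = 1L, n_prescans = 8) {
  stopifnot(inherits(phantom, "phantom_cohort"), inherits(basis, "basis_set"))
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  if (lipid_amplitude < 0) stop("lipid_amplitude must be >= 0")
  tr <- phantom$truth
  if (is.null(tr)) stop("phantom has no truth; call assign_truth_concentrations()")
  acq <- metabolite_acquisition(basis$reference_frequency, basis$carrier_ppm)
  stopifnot(acq$n_points == basis$n_points,
            acq$bandwidth_hz == basis$sampling_bandwidth)
  acq_w <- water_acquisition(water_basis$reference_frequency,
                             water_basis$carrier_ppm)
  stopifnot(acq_w$n_points == water_basis$n_points)

  motion <- identical(tr$subject_flags[subject], "motion")
  damp_hz <- extra_damping_hz + if (motion) 38 else 0

  if (is.null(noise_sd))
    noise_sd <- calibrate_noise_sd(phantom, subject, basis, relax, acq,
                                   target_snr, extra_damping_hz)

  sel <- which(phantom$brain_mask | phantom$scalp_mask)
  nv <- length(sel)
  fg <- phantom$f_gm[sel]; fw <- phantom$f_wm[sel]; fc <- phantom$f_csf[sel]

  # per-voxel basis amplitudes (compounds x voxels)
  cmp <- tr$compounds
  ee <- vapply(cmp, function(cm) {
    t1 <- relax$metabolite_t1[relax$metabolite_t1$compound == cm, ]
    e_gm <- ernst_factor(acq$flip_deg, acq$tr_ms, t1$t1_gm_ms)
    e_wm <- ernst_factor(acq$flip_deg, acq$tr_ms, t1$t1_wm_ms)
    ft <- fg + fw
    ifelse(ft > 0, (fg * e_gm + fw * e_wm) / ft, 0)
  }, numeric(nv))                     # voxels x compounds
  truth_gm <- tr$subject_tissue_mM[subject, cmp, "GM"]
  truth_wm <- tr$subject_tissue_mM[subject, cmp, "WM"]
  amps <- t(outer(fg, truth_gm) + outer(fw, truth_wm)) * t(ee)  # compounds x voxels

  met <- basis$signals[, cmp, drop = FALSE] %*% amps
  met <- met * damping_vector(acq, damp_hz)

  # scalp lipid, bleeding into peripheral brain voxels via the Hamming PSF
  set.seed((as.integer(seed) * 131 + subject * 17) %% .Machine$integer.max)
  if (lipid_amplitude > 0) {
    lip_map <- array(0, phantom$grid_shape)
    nsc <- sum(phantom$scalp_mask)
    lip_map[phantom$scalp_mask] <- lipid_amplitude *
      exp(stats::rnorm(nsc, 0, 0.25))
    lip_map <- smooth3d_hamming(lip_map, 5)
    lip_fid <- lipid_fid_signal(acq) * damping_vector(acq, damp_hz)
    met <- met + outer(as.vector(lip_fid), lip_map[sel])
  }

  if (motion) {
    cx <- phantom$coords$nx[sel]; cy <- phantom$coords$ny[sel]
    met <- met %*% diag(exp(1i * (1.5 * cx + 1.1 * cy)))
  }

  # water-reference scan
  wt <- relax$water
  e_gm <- ernst_factor(acq_w$flip_deg, acq_w$tr_ms, wt$t1_gm_ms)
  e_wm <- ernst_factor(acq_w$flip_deg, acq_w$tr_ms, wt$t1_wm_ms)
  e_cs <- ernst_factor(acq_w$flip_deg, acq_w$tr_ms, wt$t1_csf_ms)
  w_amp <- 1000 * (fg * wt$conc_gm * e_gm + fw * wt$conc_wm * e_wm +
                     fc * wt$conc_csf * e_cs)
  wat <- outer(as.vector(water_basis$signals[, 1]), w_amp)
  wat <- wat * damping_vector(acq_w, damp_hz)
  if (motion) {
    cx <- phantom$coords$nx[sel]; cy <- phantom$coords$ny[sel]
    wat <- wat %*% diag(exp(1i * (1.5 * cx + 1.1 * cy)))
  }

  cplx_noise <- function(n, m, sd) {
    matrix(complex(real = stats::rnorm(n * m, 0, sd),
                   imaginary = stats::rnorm(n * m, 0, sd)), n, m)
  }
  if (noise_sd > 0) {
    met <- met + cplx_noise(nrow(met), nv, noise_sd)
    wat <- wat + cplx_noise(nrow(wat), nv, noise_sd)
  }
  prescans <- cplx_noise(acq$n_points, n_prescans, max(noise_sd, 0))

  structure(list(
    subject = subject,
    voxel_index = sel, grid_shape = phantom$grid_shape,
    metabolite_fids = met, water_fids = wat,
    acq_met = acq, acq_water = acq_w,
    brain_mask = phantom$brain_mask, scalp_mask = phantom$scalp_mask,
    noise_sd = noise_sd, noise_prescans = prescans,
    extra_damping_hz = damp_hz, motion = motion,
    seed = as.integer(seed)
  ), class = "subject_dataset")
}

# subcutaneous lipid signal: broad lines in the 0.9-1.8 ppm band
lipid_fid_signal <- function(acq) {
  res <- resonance(c(0.90, 1.30, 1.60), c(1.5, 6.0, 1.5),
                   c(0.030, 0.035, 0.030))
  simulate_compound_fid(res, acq$bandwidth_hz, acq$readout_s, acq$delay_s,
                        acq$ref_freq_mhz, acq$carrier_ppm)
}

#' Build the single-compound water basis for the reference scan
#'
#' @param acq water-scan acquisition parameters.
#' @param t2_star apparent water T2* in seconds.
#' @return A `basis_set` with one compound, `water`.
#' @export
build_water_basis <- function(acq = water_acquisition(), t2_star = 0.05) {
  build_basis_set(list(water = resonance(4.7, 1, t2_star)), acq)
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("Subject %d dataset: %d voxels, met %d pts / water %d pts, noise sd %.3g%s\n",
              x$subject, length(x$voxel_index), nrow(x$metabolite_fids),
              nrow(x$water_fids), x$noise_sd,
              if (x$motion) " [motion]" else ""))
  invisible(x)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("Phantom %s, %d ROIs (%s)%s\n",
              paste(x$grid_shape, collapse = "x"), length(x$roi_names),
              paste(x$roi_names, collapse = ", "),
              if (!is.null(x$truth))
                sprintf(", %d subjects at %g%% inter-subject CV",
                        x$truth$n_subjects, x$truth$inter_subject_cv)
              else " (no truth)"))
  invisible(x)
}
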