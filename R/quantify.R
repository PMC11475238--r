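#' Steady-state Ernst saturation factor
#'
#' Signal factor of a spoiled steady state at repetition time TR for a pool
#' with longitudinal relaxation time T1:
#' `sin(theta) * (1 - E1) / (1 - cos(theta) * E1)` with
#' `E1 = exp(-TR/T1)`. For TR >> T1 this tends to `sin(theta)`; its argmax
#' over theta is the Ernst angle `acos(E1)`.
#'
#' @param theta_deg flip angle in degrees, in (0, 180).
#' @param tr_ms repetition time in ms.
#' @param t1_ms longitudinal relaxation time in ms.
#' @return Dimensionless saturation factor.
#' @export
ernst_factor <- function(theta_deg, tr_ms, t1_ms) {
  stopifnot(all(t1_ms > 0), all(tr_ms > 0),
            all(theta_deg > 0), all(theta_deg < 180))
  th <- theta_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  sin(th) * (1 - e1) / (1 - cos(th) * e1)
}

#' Ernst angle for given TR and T1
#'
#' @inheritParams ernst_factor
#' @return Flip angle in degrees maximising [ernst_factor()].
#' @export
ernst_angle <- function(tr_ms, t1_ms) {
  stopifnot(tr_ms > 0, t1_ms > 0)
  acos(exp(-tr_ms / t1_ms)) * 180 / pi
}

#' Default relaxation table (7 T literature values)
#'
#' Metabolite and water T1 times for GM and WM used by the saturation
#' correction, and the compartment water concentrations (mol/L) used by the
#' internal water reference: 36.1 for GM, 43.3 for WM, 53.8 for CSF. The CSF
#' water T1 defaults to 4300 ms; the macromolecular background is assigned a
#' short T1 typical of semi-solid pools.
#'
#' @param water_t1_csf_ms CSF water T1 in ms.
#' @return List with `metabolite_t1` (data.frame: compound, t1_gm_ms,
#'   t1_wm_ms) and `water` (T1s and compartment concentrations).
#' @export
default_relaxation_table <- function(water_t1_csf_ms = 4300) {
  list(
    metabolite_t1 = data.frame(
      compound = c("NAA", "tCr", "tCho", "Glu", "Gln", "mIns", "NAAG", "MM"),
      t1_gm_ms = c(1535, 1780, 1510, 1610, 1540, 1280, 1210, 500),
      t1_wm_ms = c(1545, 1740, 1320, 1750, 1740, 1190, 940, 500)
    ),
    water = list(t1_gm_ms = 2000, t1_wm_ms = 1550,
                 t1_csf_ms = water_t1_csf_ms,
                 conc_gm = 36.1, conc_wm = 43.3, conc_csf = 53.8)
  )
}

#' Voxel water content and relaxation-weighted water signal factor
#'
#' The voxel water concentration is the fraction-weighted sum of the
#' compartment molar water concentrations,
#' `f_GM*36.1 + f_WM*43.3 + f_CSF*53.8` mol/L. The effective water Ernst
#' factor is the water-content-weighted average of the per-compartment
#' Ernst factors at the water-scan TR and flip angle.
#'
#' @param fractions numeric vector `c(f_gm, f_wm, f_csf)`, each in [0, 1],
#'   sum <= 1.
#' @param relax relaxation table, see [default_relaxation_table()].
#' @param water_acq water-scan `mrsi_acq`.
#' @return List with `water_mol_per_l`, `ernst_eff` and `flagged` (TRUE when
#'   the voxel holds no water compartment at all).
#' @export
voxel_water_concentration <- function(fractions,
                                      relax = default_relaxation_table(),
                                      water_acq = water_acquisition()) {
  f <- fractions
  stopifnot(length(f) == 3, all(f >= 0), all(f <= 1), sum(f) <= 1 + 1e-9)
  wt <- relax$water
  w <- c(wt$conc_gm, wt$conc_wm, wt$conc_csf)
  total <- sum(f * w)
  if (total <= 0)
    return(list(water_mol_per_l = 0, ernst_eff = NA_real_, flagged = TRUE))
  e <- c(ernst_factor(water_acq$flip_deg, water_acq$tr_ms, wt$t1_gm_ms),
         ernst_factor(water_acq$flip_deg, water_acq$tr_ms, wt$t1_wm_ms),
         ernst_factor(water_acq$flip_deg, water_acq$tr_ms, wt$t1_csf_ms))
  list(water_mol_per_l = total, ernst_eff = sum(f * w * e) / total,
       flagged = FALSE)
}

#' Water-referenced, tissue- and T1-corrected concentration estimate
#'
#' Converts a fitted metabolite amplitude to a molar concentration using the
#' unsuppressed water reference:
#' `C_m = (A_m / A_w) * W_voxel * (E_w,eff / E_m,eff) / (1 - f_CSF)`,
#' where `W_voxel` is the voxel water concentration (in mM), `E_w,eff` the
#' water-content-weighted water Ernst factor, `E_m,eff` the GM/WM
#' tissue-fraction-weighted metabolite Ernst factor, and the `1/(1-f_CSF)`
#' term refers the metabolite signal to the tissue (non-CSF) volume, CSF
#' being treated as metabolite-free. The estimate is invariant to a common
#' receiver gain applied to both scans.
#'
#' @param met_amp fitted metabolite amplitude (>= 0).
#' @param water_amp fitted water amplitude (> 0).
#' @param fractions `c(f_gm, f_wm, f_csf)`.
#' @param compound compound name (must be in the relaxation table).
#' @param relax relaxation table.
#' @param met_acq metabolite-scan acquisition.
#' @param water_acq water-scan acquisition.
#' @return Concentration in mM, or `NA` with attribute `"flagged"` when the
#'   voxel contains no tissue (f_CSF ~ 1).
#' @export
estimate_concentration <- function(met_amp, water_amp, fractions, compound,
                                   relax = default_relaxation_table(),
                                   met_acq = metabolite_acquisition(),
                                   water_acq = water_acquisition()) {
  stopifnot(water_amp > 0, met_amp >= 0)
  f <- fractions
  f_tis <- f[1] + f[2]
  if (f_tis <= 1e-6) {
    out <- NA_real_; attr(out, "flagged") <- "no tissue (f_CSF ~ 1)"
    return(out)
  }
  wm <- voxel_water_concentration(f, relax, water_acq)
  if (wm$flagged) {
    out <- NA_real_; attr(out, "flagged") <- "no water compartment"
    return(out)
  }
  t1 <- relax$metabolite_t1[relax$metabolite_t1$compound == compound, ]
  if (nrow(t1) == 0) stop("missing T1 entry for compound: ", compound)
  e_m <- (f[1] * ernst_factor(met_acq$flip_deg, met_acq$tr_ms, t1$t1_gm_ms) +
            f[2] * ernst_factor(met_acq$flip_deg, met_acq$tr_ms, t1$t1_wm_ms)) /
    f_tis
  (met_amp / water_amp) * (wm$water_mol_per_l * 1000) *
    (wm$ernst_eff / e_m) / (1 - f[3])
}

#' Median-absolute-deviation outlier filter
#'
#' Excludes values deviating from the median by more than `k` raw (unscaled)
#' median absolute deviations. With a degenerate spread (MAD = 0) while
#' distinct values are present, values differing from the median by more
#' than a relative tolerance are excluded instead (and a message logged).
#'
#' @param values numeric vector of per-voxel fit values (one compound).
#' @param k MAD multiplier (default 13).
#' @param rel_tol relative tolerance for the degenerate-MAD fallback.
#' @return Logical exclusion mask (`TRUE` = excluded); `NA` values are never
#'   marked excluded but are ignored in the median/MAD.
#' @export
mad_outlier_filter <- function(values, k = 13, rel_tol = 1e-6) {
  fin <- is.finite(values)
  if (sum(fin) < 5) stop("need at least 5 finite values")
  med <- stats::median(values[fin])
  mad_raw <- stats::median(abs(values[fin] - med))
  excl <- rep(FALSE, length(values))
  if (mad_raw == 0) {
    dev <- abs(values - med) > rel_tol * max(abs(med), 1)
    if (any(dev[fin])) {
      message("mad_outlier_filter: MAD = 0 with outliers present; ",
              "falling back to relative-tolerance exclusion")
      excl[fin] <- dev[fin]
    }
    return(excl)
  }
  excl[fin] <- abs(values[fin] - med) > k * mad_raw
  excl
}

#' Spectral quality thresholds
#'
#' Voxels are kept only when tCr SNR >= `snr_min`, tCr linewidth
#' <= `fwhm_max_ppm`, the compound's CRLB <= `crlb_max_percent`, and the fit
#' value survives the `mad_k`-MAD outlier filter.
#'
#' @param snr_min minimum tCr SNR.
#' @param fwhm_max_ppm maximum tCr FWHM in ppm.
#' @param crlb_max_percent maximum per-compound CRLB in percent.
#' @param mad_k MAD multiplier of the fit-value outlier filter.
#' @return List of thresholds.
#' @export
quality_thresholds <- function(snr_min = 5, fwhm_max_ppm = 0.15,
                               crlb_max_percent = 40, mad_k = 13) {
  stopifnot(snr_min > 0, fwhm_max_ppm > 0, crlb_max_percent > 0, mad_k > 0)
  list(snr_min = snr_min, fwhm_max_ppm = fwhm_max_ppm,
       crlb_max_percent = crlb_max_percent, mad_k = mad_k)
}

#' Build the spectral quality mask
#'
#' Applies the four exclusion rules to per-voxel fit maps. The SNR and
#' linewidth rules are global (based on the tCr fit); the CRLB and MAD rules
#' are per compound. Per-rule exclusion counts are returned alongside the
#' masks.
#'
#' @param fit_maps list with numeric vectors (one entry per fitted voxel):
#'   `snr`, `fwhm_ppm`, and per-compound `crlb` and `amplitude` matrices
#'   (voxels x compounds, named columns).
#' @param thresholds from [quality_thresholds()].
#' @return List with `pass` (logical matrix voxels x compounds), `counts`
#'   (per-rule exclusion counts) and the thresholds used.
#' @export
build_quality_mask <- function(fit_maps, thresholds = quality_thresholds()) {
  for (req in c("snr", "fwhm_ppm", "crlb", "amplitude"))
    if (is.null(fit_maps[[req]])) stop("missing map: ", req)
  snr_ok <- fit_maps$snr >= thresholds$snr_min
  fwhm_ok <- fit_maps$fwhm_ppm <= thresholds$fwhm_max_ppm
  crlb <- fit_maps$crlb
  amp <- fit_maps$amplitude
  stopifnot(is.matrix(crlb), is.matrix(amp),
            identical(colnames(crlb), colnames(amp)))
  nv <- nrow(crlb)
  pass <- matrix(NA, nv, ncol(crlb), dimnames = dimnames(crlb))
  counts <- list(snr = sum(!snr_ok, na.rm = TRUE),
                 fwhm = sum(!fwhm_ok, na.rm = TRUE),
                 crlb = integer(0), mad = integer(0))
  for (cm in colnames(crlb)) {
    crlb_ok <- is.finite(crlb[, cm]) & crlb[, cm] <= thresholds$crlb_max_percent
    mad_excl <- mad_outlier_filter(amp[, cm], k = thresholds$mad_k)
    pass[, cm] <- snr_ok & fwhm_ok & crlb_ok & !mad_excl
    counts$crlb[cm] <- sum(!crlb_ok)
    counts$mad[cm] <- sum(mad_excl)
  }
  list(pass = pass, counts = counts, thresholds = thresholds)
}
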