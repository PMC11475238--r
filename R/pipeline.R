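#' Pipeline configuration
#'
#' Collects every knob of the end-to-end synthetic study in one validated
#' list: phantom geometry, cohort size and inter-subject variability,
#' acquisition-derived constants, lipid stage, fitting and quality
#' thresholds, and the root seed from which all per-subject/per-stage
#' random streams are derived.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param grid_shape phantom grid (min 16 x 16 x 8).
#' @param voxel_mm nominal voxel size in mm.
#' @param inter_subject_cv true inter-subject CV in percent.
#' @param tissue_means GM/WM tissue means, see [default_tissue_means()].
#' @param relax relaxation table, see [default_relaxation_table()].
#' @param thresholds quality thresholds, see [quality_thresholds()].
#' @param target_snr generator tCr SNR target (noise calibration).
#' @param noise_sd explicit generator noise SD (overrides `target_snr`).
#' @param lipid_removal lipid-removal stage on/off.
#' @param lipid_beta `"auto"` or numeric weight.
#' @param lipid_amplitude generator scalp lipid amplitude.
#' @param extra_damping_hz generator line broadening in Hz.
#' @param motion_subjects indices of subjects simulated with motion.
#' @param voxels_per_roi number of voxels sampled per ROI for fitting
#'   (`NULL` fits every brain voxel).
#' @param subject_min_pass minimum fraction of fitted voxels passing the
#'   quality mask for a subject to be retained.
#' @param seed root integer seed.
#' @param roi_spec ROI specification, see [default_roi_spec()].
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 5, grid_shape = c(32, 32, 16),
                            voxel_mm = 3.4, inter_subject_cv = 10,
                            tissue_means = default_tissue_means(),
                            relax = default_relaxation_table(),
                            thresholds = quality_thresholds(),
                            target_snr = 11, noise_sd = NULL,
                            lipid_removal = TRUE, lipid_beta = "auto",
                            lipid_amplitude = 30, extra_damping_hz = 12,
                            motion_subjects = integer(0),
                            voxels_per_roi = 12, subject_min_pass = 0.5,
                            seed = 1L, roi_spec = default_roi_spec()) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Fails before any stage runs when a field is out of range.
#' @param cfg a `pipeline_config`.
#' @return `cfg` invisibly.
#' @export
validate_pipeline_config <- function(cfg) {
  if (cfg$n_subjects < 2) stop("config invalid: n_subjects must be >= 2")
  if (length(cfg$grid_shape) != 3) stop("config invalid: grid_shape")
  if (cfg$inter_subject_cv < 0) stop("config invalid: inter_subject_cv")
  if (!is.null(cfg$noise_sd) && cfg$noise_sd < 0)
    stop("config invalid: noise_sd")
  if (cfg$lipid_amplitude < 0) stop("config invalid: lipid_amplitude")
  if (any(cfg$motion_subjects < 1 | cfg$motion_subjects > cfg$n_subjects))
    stop("config invalid: motion_subjects out of range")
  invisible(cfg)
}

# deterministic substream seed (double arithmetic, result below 2^31)
substream_seed <- function(root, stage, index = 0L) {
  as.integer((as.numeric(root) * 2654435 + as.numeric(stage) * 97003 +
                as.numeric(index) * 1009) %% 2147483647)
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> lipid removal -> spectral fit -> water-referenced
#' quantification -> quality mask -> ROI means -> cohort statistics.
#' Deterministic given the config (all randomness flows from the root seed
#' through named substreams). Subjects whose quality-mask pass fraction
#' falls below `subject_min_pass` (e.g. simulated motion) are excluded
#' from the cohort statistics and listed in the report.
#'
#' @param config a `pipeline_config`.
#' @return Report list: `cohort` (concentration/ratio/CV tables),
#'   `roi_classification`, `qualification`, `subject_tables`,
#'   `excluded_subjects`, `exclusion_counts`, `timings_s`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_pipeline_config(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- t1 - t0
    t0 <<- t1
  }

  phantom <- build_phantom(config$grid_shape, config$voxel_mm,
                           config$roi_spec,
                           seed = substream_seed(config$seed, 1L))
  phantom <- assign_truth_concentrations(
    phantom, config$tissue_means, config$inter_subject_cv,
    config$n_subjects, seed = substream_seed(config$seed, 2L))
  for (s in config$motion_subjects)
    phantom <- flag_motion_subject(phantom, s)
  basis <- build_basis_set(default_resonance_table(),
                           metabolite_acquisition())
  wbasis <- build_water_basis()
  tick("setup")

  # fitted voxel sample: per-ROI draw, shared across subjects
  set.seed(substream_seed(config$seed, 3L))
  brain_idx <- which(phantom$brain_mask & phantom$f_bg < 0.05)
  sample_idx <- if (is.null(config$voxels_per_roi)) brain_idx else {
    unlist(lapply(seq_along(phantom$roi_names), function(l) {
      vx <- which(phantom$roi_labels == l)
      vx[sample.int(length(vx), min(config$voxels_per_roi, length(vx)))]
    }))
  }

  mets <- setdiff(phantom$truth$compounds, "MM")
  n_roi <- length(phantom$roi_names)
  roi_means <- array(NA_real_,
                     c(config$n_subjects, n_roi, length(mets)),
                     dimnames = list(NULL, phantom$roi_names, mets))
  roi_pass <- matrix(NA_real_, config$n_subjects, n_roi,
                     dimnames = list(NULL, phantom$roi_names))
  met_pass <- array(NA_real_, c(config$n_subjects, n_roi, length(mets)),
                    dimnames = list(NULL, phantom$roi_names, mets))
  brain_fit_pct <- matrix(NA_real_, config$n_subjects, length(mets),
                          dimnames = list(NULL, mets))
  subject_tables <- vector("list", config$n_subjects)
  excluded <- character(0)
  excl_counts <- vector("list", config$n_subjects)

  for (s in seq_len(config$n_subjects)) {
    ds <- synthesize_subject(
      phantom, s, basis, wbasis, config$relax,
      noise_sd = config$noise_sd, target_snr = config$target_snr,
      lipid_amplitude = config$lipid_amplitude,
      extra_damping_hz = config$extra_damping_hz,
      seed = substream_seed(config$seed, 4L, s))
    vox <- match(sample_idx, ds$voxel_index)
    fits <- fit_dataset(ds, basis, wbasis, voxels = vox,
                        lipid_removal = config$lipid_removal,
                        lipid_beta = config$lipid_beta)
    conc <- quantify_fits(fits, phantom, mets, config$relax,
                          ds$acq_met, ds$acq_water)
    qm <- build_quality_mask(
      list(snr = fits$table$snr, fwhm_ppm = fits$table$fwhm_ppm,
           crlb = fits$crlb[, mets, drop = FALSE],
           amplitude = fits$amplitudes[, mets, drop = FALSE]),
      config$thresholds)
    excl_counts[[s]] <- qm$counts

    labels <- phantom$roi_labels[fits$voxel_index]
    for (l in seq_len(n_roi)) {
      in_roi <- labels == l
      if (!any(in_roi)) next
      roi_pass[s, l] <- roi_pass_fraction(fits$crlb, in_roi,
                                          threshold =
                                            config$thresholds$crlb_max_percent)
      for (m in mets) {
        met_pass[s, l, m] <- metabolite_pass_fraction(fits$crlb, in_roi, m)
        rm_ <- roi_mean_concentration(conc[, m], qm$pass[, m], in_roi)
        roi_means[s, l, m] <- rm_$mean
      }
    }
    brain_fit_pct[s, ] <- 100 * colMeans(fits$amplitudes[, mets,
                                                         drop = FALSE] > 0)
    pass_frac <- mean(qm$pass[, "tCr"], na.rm = TRUE)
    subject_tables[[s]] <- list(fits = fits$table, lipid_beta = fits$lipid_beta,
                                pass_fraction = pass_frac,
                                water = fits$water)
    if (pass_frac < config$subject_min_pass)
      excluded <- c(excluded, sprintf("subject %d (pass fraction %.2f)",
                                      s, pass_frac))
    tick(sprintf("subject_%d", s))
  }

  keep <- setdiff(seq_len(config$n_subjects),
                  as.integer(sub("subject (\\d+).*", "\\1", excluded)))
  if (length(keep) < 2) stop("fewer than 2 subjects retained")
  cohort <- cohort_statistics(roi_means[keep, , , drop = FALSE])
  pooled_pass <- colMeans(roi_pass[keep, , drop = FALSE], na.rm = TRUE)
  classification <- data.frame(
    roi = phantom$roi_names,
    pass_fraction = as.numeric(pooled_pass),
    classification = classify_roi(pooled_pass))
  qual <- metabolite_qualification(
    apply(met_pass[keep, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE),
    colMeans(brain_fit_pct[keep, , drop = FALSE]))
  tick("cohort_stats")

  list(cohort = cohort,
       roi_classification = classification,
       qualification = qual,
       roi_means = roi_means,
       subject_tables = subject_tables,
       excluded_subjects = excluded,
       exclusion_counts = excl_counts,
       timings_s = timings,
       provenance = list(seed = config$seed,
                         config_yaml = yaml::as.yaml(unclass(
                           config[setdiff(names(config),
                                          c("tissue_means", "relax"))]))))
}

# per-voxel water-referenced concentrations for the fitted voxel set
quantify_fits <- function(fits, phantom, mets, relax, met_acq, water_acq) {
  nv <- length(fits$voxel_index)
  conc <- matrix(NA_real_, nv, length(mets),
                 dimnames = list(NULL, mets))
  for (i in seq_len(nv)) {
    v <- fits$voxel_index[i]
    f <- c(phantom$f_gm[v], phantom$f_wm[v], phantom$f_csf[v])
    aw <- fits$water$amplitude[i]
    if (!is.finite(aw) || aw <= 0 || isTRUE(fits$water$flagged[i])) next
    for (m in mets) {
      cm <- estimate_concentration(fits$amplitudes[i, m], aw, f, m,
                                   relax, met_acq, water_acq)
      conc[i, m] <- as.numeric(cm)
    }
  }
  conc
}

#' Write pipeline report tables to CSV
#'
#' @param report from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    concentration = file.path(out_dir, "cohort_concentration.csv"),
    ratio = file.path(out_dir, "cohort_ratio_to_tcr.csv"),
    classification = file.path(out_dir, "roi_classification.csv"),
    qualification = file.path(out_dir, "metabolite_qualification.csv"))
  utils::write.csv(report$cohort$concentration, paths["concentration"],
                   row.names = FALSE)
  utils::write.csv(report$cohort$ratio, paths["ratio"], row.names = FALSE)
  utils::write.csv(report$roi_classification, paths["classification"],
                   row.names = FALSE)
  utils::write.csv(report$qualification, paths["qualification"],
                   row.names = FALSE)
  writeLines(c(report$provenance$config_yaml,
               sprintf("root_seed: %d", report$provenance$seed)),
             file.path(out_dir, "provenance.yaml"))
  invisible(paths)
}

#' Write a 3D map as NIfTI
#'
#' Thin wrapper over the RNifti package (suggested dependency) for
#' exporting fraction, truth, concentration or quality maps.
#'
#' @param map 3D numeric array.
#' @param path output file path (`.nii` / `.nii.gz`).
#' @param voxel_mm isotropic voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path, voxel_mm = 3.4) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  img <- RNifti::asNifti(map, pixdim = rep(voxel_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}
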