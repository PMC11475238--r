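#' Joint CRLB pass fraction of an ROI
#'
#' Percentage of ROI voxels where the CRLBs of all of NAA, tCr, tCho and
#' mIns (or any supplied compound set) are below the threshold.
#'
#' @param crlb matrix (voxels x compounds, named columns) of CRLB
#'   percentages.
#' @param roi_mask logical vector selecting the ROI rows.
#' @param compounds compounds that must jointly pass.
#' @param threshold CRLB threshold in percent (strict `<`).
#' @return Pass fraction in percent.
#' @export
roi_pass_fraction <- function(crlb, roi_mask,
                              compounds = c("NAA", "tCr", "tCho", "mIns"),
                              threshold = 40) {
  stopifnot(is.matrix(crlb))
  if (!any(roi_mask)) stop("ROI is empty")
  missing <- setdiff(compounds, colnames(crlb))
  if (length(missing)) stop("missing CRLB columns: ",
                            paste(missing, collapse = ", "))
  sub <- crlb[roi_mask, compounds, drop = FALSE]
  ok <- rowSums(is.finite(sub) & sub < threshold) == length(compounds)
  100 * sum(ok) / sum(roi_mask)
}

#' Per-metabolite pass fraction of an ROI
#'
#' Percentage of ROI voxels with the compound's CRLB below a threshold
#' (20% for the high-SNR set NAA/tCr/tCho/mIns, 40% otherwise, by
#' convention of the regional quality tables).
#'
#' @inheritParams roi_pass_fraction
#' @param compound one compound name.
#' @return Pass fraction in percent.
#' @export
metabolite_pass_fraction <- function(crlb, roi_mask, compound,
                                     threshold = if (compound %in%
                                       c("NAA", "tCr", "tCho", "mIns"))
                                       20 else 40) {
  if (!any(roi_mask)) stop("ROI is empty")
  v <- crlb[roi_mask, compound]
  100 * sum(is.finite(v) & v < threshold) / sum(roi_mask)
}

#' Classify an ROI from its joint pass fraction
#'
#' `good` at >= 80%, `acceptable` at >= 66%, otherwise `rejected`.
#' Rejected ROIs are excluded from cohort statistics.
#'
#' @param pass_fraction percentage in [0, 100].
#' @param good_min,acceptable_min classification cut-offs in percent.
#' @return One of `"good"`, `"acceptable"`, `"rejected"`.
#' @export
classify_roi <- function(pass_fraction, good_min = 80, acceptable_min = 66) {
  stopifnot(all(pass_fraction >= 0), all(pass_fraction <= 100))
  out <- ifelse(pass_fraction >= good_min, "good",
                ifelse(pass_fraction >= acceptable_min, "acceptable",
                       "rejected"))
  out
}

#' Qualify metabolites for the cohort analysis
#'
#' A metabolite is discarded when it was fit in fewer than
#' `min_brain_percent` of brain voxels; of the remainder, it qualifies when
#' its mean pass fraction over all retained ROIs is strictly greater than
#' `qualify_percent`.
#'
#' @param roi_pass matrix (ROIs x metabolites) of per-ROI pass fractions in
#'   percent.
#' @param brain_fit_percent named vector: percentage of brain voxels in
#'   which each metabolite was fit (non-zero amplitude).
#' @param min_brain_percent discard threshold (default 10).
#' @param qualify_percent qualification threshold on the ROI mean
#'   (default 66, strict `>`).
#' @return data.frame with per-metabolite mean pass fraction, discard and
#'   qualification flags.
#' @export
metabolite_qualification <- function(roi_pass, brain_fit_percent,
                                     min_brain_percent = 10,
                                     qualify_percent = 66) {
  stopifnot(is.matrix(roi_pass), nrow(roi_pass) >= 1)
  mets <- colnames(roi_pass)
  stopifnot(all(mets %in% names(brain_fit_percent)))
  mean_pass <- colMeans(roi_pass)
  discarded <- brain_fit_percent[mets] < min_brain_percent
  qualified <- !discarded & mean_pass > qualify_percent
  data.frame(metabolite = mets,
             brain_fit_percent = as.numeric(brain_fit_percent[mets]),
             mean_roi_pass = as.numeric(mean_pass),
             discarded = as.logical(discarded),
             qualified = as.logical(qualified),
             row.names = NULL)
}

#' Mean concentration of an ROI over quality-passing voxels
#'
#' @param conc numeric vector of per-voxel concentrations.
#' @param quality_mask logical vector of quality-passing voxels.
#' @param roi_mask logical vector selecting the ROI.
#' @return List with `mean`, `sd`, `n` (passing voxels); `flagged = TRUE`
#'   with `NA` statistics when no voxel passes.
#' @export
roi_mean_concentration <- function(conc, quality_mask, roi_mask) {
  sel <- roi_mask & quality_mask & is.finite(conc)
  if (!any(sel))
    return(list(mean = NA_real_, sd = NA_real_, n = 0L, flagged = TRUE))
  v <- conc[sel]
  list(mean = mean(v), sd = stats::sd(v), n = length(v), flagged = FALSE)
}

#' Metabolite-to-tCr ratios per subject and their cohort summary
#'
#' The ratio is formed per subject as the subject's ROI-mean metabolite
#' concentration divided by the subject's ROI-mean tCr, then summarised
#' over subjects.
#'
#' @param met_means per-subject ROI means of the metabolite.
#' @param tcr_means per-subject ROI means of tCr (same subjects).
#' @return List with `ratios` (per subject), `mean`, `sd`; `flagged` when
#'   any tCr mean is non-positive.
#' @export
ratio_to_tcr <- function(met_means, tcr_means) {
  stopifnot(length(met_means) == length(tcr_means))
  ok <- is.finite(met_means) & is.finite(tcr_means)
  if (any(tcr_means[ok] <= 0))
    return(list(ratios = rep(NA_real_, length(met_means)),
                mean = NA_real_, sd = NA_real_, flagged = TRUE))
  r <- ifelse(ok, met_means / tcr_means, NA_real_)
  list(ratios = r, mean = mean(r[ok]), sd = stats::sd(r[ok]),
       flagged = FALSE)
}

#' Inter-subject coefficient of variation
#'
#' `100 * sample SD / mean` of the per-subject ROI means.
#'
#' @param subject_means numeric vector of per-subject ROI means (>= 2
#'   finite values).
#' @return CV in percent; `NA` with attribute `"flagged"` when the mean is
#'   non-positive.
#' @export
inter_subject_cv <- function(subject_means) {
  v <- subject_means[is.finite(subject_means)]
  if (length(v) < 2) stop("need at least 2 subjects")
  m <- mean(v)
  if (m <= 0) {
    out <- NA_real_; attr(out, "flagged") <- "non-positive mean"
    return(out)
  }
  100 * stats::sd(v) / m
}

#' Column summary (mean, min, max) of per-ROI values
#'
#' Mirrors the summary rows of the cohort report tables. `digits` controls
#' the report rounding: 0 for CV percentages, 2 for concentrations in mM.
#'
#' @param values numeric vector of per-ROI values.
#' @param digits rounding applied to the summary (`NULL` for none).
#' @return Named vector `c(mean, min, max)`.
#' @export
summarize_column <- function(values, digits = NULL) {
  stopifnot(length(values) >= 1)
  out <- c(mean = mean(values), min = min(values), max = max(values))
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Nearest-neighbour resampling of a map onto a label grid
#'
#' Resamples a 3D map to the shape of a (typically finer) label grid under
#' a shared field of view: target voxel centres are mapped to the nearest
#' source voxel. No new values are created.
#'
#' @param map 3D numeric array.
#' @param target_shape integer vector of 3 target dimensions.
#' @return Array of shape `target_shape`.
#' @export
resample_map_to_labels <- function(map, target_shape) {
  d_in <- dim(map)
  stopifnot(length(d_in) == 3, length(target_shape) == 3)
  target_shape <- as.integer(target_shape)
  if (any(target_shape < 1)) stop("grids do not overlap")
  idx <- lapply(1:3, function(ax) {
    centres <- (seq_len(target_shape[ax]) - 0.5) / target_shape[ax]
    pmin(pmax(ceiling(centres * d_in[ax]), 1L), d_in[ax])
  })
  map[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Cohort statistics over subjects and ROIs
#'
#' Aggregates per-subject ROI means into the cohort report: inter-subject
#' mean of means, SD and CV per ROI and metabolite, plus ratios to tCr.
#' Subjects or (subject, ROI) pairs listed in the exclusion manifest are
#' dropped before averaging.
#'
#' @param roi_means 3D array subjects x ROIs x metabolites (dimnames set)
#'   of per-subject ROI mean concentrations.
#' @param exclusions optional data.frame with columns `subject` and `roi`
#'   (`NA` roi = exclude the whole subject).
#' @return List with data.frames `concentration` (mean/sd/cv per ROI and
#'   metabolite) and `ratio` (to tCr), and `n_subjects_used` per ROI.
#' @export
cohort_statistics <- function(roi_means, exclusions = NULL) {
  stopifnot(length(dim(roi_means)) == 3)
  subs <- seq_len(dim(roi_means)[1])
  rois <- dimnames(roi_means)[[2]]
  mets <- dimnames(roi_means)[[3]]
  use <- matrix(TRUE, length(subs), length(rois),
                dimnames = list(NULL, rois))
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    for (i in seq_len(nrow(exclusions))) {
      s <- exclusions$subject[i]; r <- exclusions$roi[i]
      if (is.na(r)) use[s, ] <- FALSE else use[s, r] <- FALSE
    }
  }
  conc <- expand.grid(roi = rois, metabolite = mets,
                      stringsAsFactors = FALSE)
  conc$mean <- NA_real_; conc$sd <- NA_real_; conc$cv_percent <- NA_real_
  rat <- conc[conc$metabolite != "tCr", ]
  for (i in seq_len(nrow(conc))) {
    v <- roi_means[, conc$roi[i], conc$metabolite[i]]
    v <- v[use[, conc$roi[i]] & is.finite(v)]
    if (length(v) >= 2) {
      conc$mean[i] <- mean(v); conc$sd[i] <- stats::sd(v)
      conc$cv_percent[i] <- inter_subject_cv(v)
    }
  }
  if (nrow(rat) > 0) {
    rat$mean <- NA_real_; rat$sd <- NA_real_; rat$cv_percent <- NA_real_
    for (i in seq_len(nrow(rat))) {
      keep <- use[, rat$roi[i]]
      mm <- roi_means[, rat$roi[i], rat$metabolite[i]][keep]
      tc <- roi_means[, rat$roi[i], "tCr"][keep]
      rr <- ratio_to_tcr(mm, tc)
      if (!rr$flagged && sum(is.finite(rr$ratios)) >= 2) {
        rat$mean[i] <- rr$mean; rat$sd[i] <- rr$sd
        rat$cv_percent[i] <- inter_subject_cv(rr$ratios)
      }
    }
  }
  list(concentration = conc, ratio = rat,
       n_subjects_used = colSums(use))
}
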