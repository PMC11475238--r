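#' Frequency-domain spectra of a subject dataset
#'
#' Transforms the stored per-voxel FIDs of one scan with the package's
#' centred unitary DFT.
#'
#' @param dataset a `subject_dataset`.
#' @param scan `"metabolite"` or `"water"`.
#' @return List with `spectra` (complex matrix, frequency x voxel), `ppm`
#'   axis and the voxel index into the 3D grid.
#' @export
subject_spectra <- function(dataset, scan = c("metabolite", "water")) {
  scan <- match.arg(scan)
  fids <- if (scan == "metabolite") dataset$metabolite_fids else
    dataset$water_fids
  acq <- if (scan == "metabolite") dataset$acq_met else dataset$acq_water
  n <- nrow(fids)
  sp <- stats::mvfft(fids) / sqrt(n)
  sp <- apply(sp, 2, fftshift_vec)
  list(spectra = sp,
       ppm = spectral_ppm_axis(n, acq$bandwidth_hz, acq$ref_freq_mhz,
                               acq$carrier_ppm),
       voxel_index = dataset$voxel_index)
}

#' Extract the lipid basis from scalp voxels
#'
#' Collects the metabolite-scan spectra of all scalp-mask voxels; these
#' span the lipid contamination subspace used by the L2 removal operator.
#' Optionally the collection is compressed to its top singular vectors
#' (scaled by their singular values, so the operator weighting is
#' preserved).
#'
#' @param dataset a `subject_dataset` (its scalp mask is used by default).
#' @param scalp_mask optional logical 3D array overriding the stored mask.
#' @param n_components optional number of SVD components to keep.
#' @return An object of class `lipid_basis`: `spectra` (frequency x source
#'   voxels or components), `source_voxel_count`, `ppm`.
#' @export
extract_lipid_basis <- function(dataset, scalp_mask = NULL,
                                n_components = NULL) {
  stopifnot(inherits(dataset, "subject_dataset"))
  mask <- if (is.null(scalp_mask)) dataset$scalp_mask else scalp_mask
  sel <- which(mask[dataset$voxel_index])
  if (length(sel) == 0) stop("scalp mask is empty")
  sp <- subject_spectra(dataset, "metabolite")
  L <- sp$spectra[, sel, drop = FALSE]
  if (!is.null(n_components)) {
    n_components <- min(n_components, ncol(L))
    sv <- svd(L, nu = n_components, nv = 0)
    L <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  }
  new_lipid_basis(L, length(sel), sp$ppm)
}

new_lipid_basis <- function(L, n_source, ppm) {
  sv <- if (any(Mod(L) > 0)) svd(L, nv = 0) else
    list(u = matrix(0i, nrow(L), 1), d = 0)
  structure(list(spectra = L, source_voxel_count = n_source, ppm = ppm,
                 svd_u = sv$u, svd_d = sv$d), class = "lipid_basis")
}

#' L2-regularised lipid removal
#'
#' Applies the linear operator `(I + beta * L L^H)^{-1}` to each spectrum,
#' where the columns of `L` are the lipid basis spectra. Components of the
#' input lying in the lipid subspace are shrunk towards zero with strength
#' `beta`; the operator is the identity at `beta = 0` and never increases
#' the norm. Evaluated through the SVD of the basis,
#' `cleaned = s - U diag(beta d_i^2 / (1 + beta d_i^2)) U^H s`, which is
#' exact and numerically stable for arbitrarily large `beta`.
#'
#' @param spectra complex vector or matrix (frequency x voxels).
#' @param lipid_basis a `lipid_basis`.
#' @param beta regularisation weight, >= 0.
#' @return Cleaned spectra, same shape as the input.
#' @export
l2_lipid_removal <- function(spectra, lipid_basis, beta) {
  stopifnot(inherits(lipid_basis, "lipid_basis"), beta >= 0)
  vec <- is.null(dim(spectra))
  s <- if (vec) matrix(spectra, ncol = 1) else spectra
  if (nrow(s) != nrow(lipid_basis$spectra))
    stop("dimension mismatch: spectrum has ", nrow(s),
         " points, lipid basis ", nrow(lipid_basis$spectra))
  if (beta == 0) return(spectra)
  U <- lipid_basis$svd_u
  if (is.null(U)) {
    sv <- svd(lipid_basis$spectra, nv = 0)
    U <- sv$u; d <- sv$d
  } else d <- lipid_basis$svd_d
  shrink <- beta * d^2 / (1 + beta * d^2)
  out <- s - U %*% (shrink * (Conj(t(U)) %*% s))
  if (vec) as.vector(out) else out
}

#' Spectral energy inside a ppm band
#'
#' @param spectra complex vector or matrix (frequency x voxels).
#' @param ppm ppm axis.
#' @param band closed ppm interval `c(lo, hi)` (default the lipid band
#'   1.2-1.8 ppm).
#' @return Energy (sum of squared magnitudes) per spectrum.
#' @export
band_energy <- function(spectra, ppm, band = c(1.2, 1.8)) {
  sel <- ppm >= band[1] & ppm <= band[2]
  s <- if (is.null(dim(spectra))) matrix(spectra, ncol = 1) else spectra
  colSums(Mod(s[sel, , drop = FALSE])^2)
}

#' Choose the lipid-removal weight automatically
#'
#' Bisection on log(beta) until the residual lipid-band (1.2-1.8 ppm)
#' signal of the supplied brain spectra drops to the target fraction of
#' its pre-removal value. The fraction is measured on the RMS amplitude
#' (square root of the pooled band energy): residual lipid biases the
#' spectral fit in proportion to its amplitude, not its energy, so the
#' amplitude scale is the one on which a tolerable residual is set.
#' Returns the smallest probed beta achieving the target (or the bracket
#' maximum when the target is unreachable, e.g. when the band is dominated
#' by macromolecular signal that lies outside the lipid subspace).
#'
#' @param brain_spectra complex matrix of in-brain spectra.
#' @param lipid_basis a `lipid_basis`.
#' @param target_fraction residual RMS amplitude fraction (default 0.05).
#' @param band lipid ppm band.
#' @param max_iter bisection iterations.
#' @return Regularisation weight beta.
#' @export
auto_lipid_beta <- function(brain_spectra, lipid_basis,
                            target_fraction = 0.05, band = c(1.2, 1.8),
                            max_iter = 60) {
  e0 <- mean(band_energy(brain_spectra, lipid_basis$ppm, band))
  if (e0 <= 0) return(0)
  frac <- function(b) {
    sqrt(mean(band_energy(l2_lipid_removal(brain_spectra, lipid_basis, b),
                          lipid_basis$ppm, band)) / e0)
  }
  lo <- -12; hi <- 12                       # log10 beta bracket
  if (frac(10^hi) > target_fraction) return(10^hi)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (frac(10^mid) > target_fraction) lo <- mid else hi <- mid
    if (hi - lo < 1e-3) break
  }
  10^hi
}

#' Projection of spectra onto the lipid subspace
#'
#' Orthogonal projection onto the column space of the lipid basis; used to
#' quantify how much lipid-subspace signal survives removal.
#'
#' @param spectra complex vector or matrix.
#' @param lipid_basis a `lipid_basis`.
#' @return Projected spectra, same shape as input.
#' @export
lipid_subspace_projection <- function(spectra, lipid_basis) {
  vec <- is.null(dim(spectra))
  s <- if (vec) matrix(spectra, ncol = 1) else spectra
  L <- lipid_basis$spectra
  sv <- svd(L)
  keep <- sv$d > max(sv$d) * 1e-10
  Q <- sv$u[, keep, drop = FALSE]
  out <- Q %*% (Conj(t(Q)) %*% s)
  if (vec) as.vector(out) else out
}

#' @export
print.lipid_basis <- function(x, ...) {
  cat(sprintf("Lipid basis: %d spectra from %d scalp voxels\n",
              ncol(x$spectra), x$source_voxel_count))
  invisible(x)
}
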