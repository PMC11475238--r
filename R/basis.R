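#' Define a single Lorentzian resonance
#'
#' A resonance is a Lorentzian line at a chemical shift, with a relative
#' amplitude (proportional to the number of contributing protons) and an
#' apparent transverse relaxation time T2* that sets its linewidth
#' (FWHM in Hz = 1 / (pi * T2*)).
#'
#' @param chemical_shift position in ppm, within 0-10.
#' @param relative_amplitude dimensionless proton weighting, > 0.
#' @param t2_star apparent T2* in seconds, > 0.
#' @return A one-row data.frame describing the resonance.
#' @export
resonance <- function(chemical_shift, relative_amplitude = 1, t2_star = 0.06) {
  stopifnot(is.numeric(chemical_shift), is.numeric(relative_amplitude),
            is.numeric(t2_star))
  if (any(chemical_shift < 0 | chemical_shift > 10))
    stop("chemical_shift must lie within 0-10 ppm")
  if (any(relative_amplitude <= 0)) stop("relative_amplitude must be > 0")
  if (any(t2_star <= 0)) stop("t2_star must be > 0")
  data.frame(chemical_shift = chemical_shift,
             relative_amplitude = relative_amplitude,
             t2_star = t2_star)
}

#' Built-in resonance table (singlet/simple-multiplet approximation)
#'
#' Chemical-shift positions and proton weightings for the main brain
#' metabolites, approximated as singlets or small groups of Lorentzians.
#' This is a deliberately simple parameterisation: coupled spin systems are
#' represented by a few lines at their main multiplet positions rather than
#' by a density-matrix simulation. The macromolecular background ("MM") is a
#' set of broad, short-T2* Lorentzians between 0.9 and 3.9 ppm.
#'
#' @param metabolite_t2_star default metabolite T2* in seconds.
#' @param mm_t2_star T2* of the macromolecular background lines, seconds.
#' @param include_mm include the macromolecular background compound.
#' @return Named list mapping compound name to a resonance data.frame.
#' @export
default_resonance_table <- function(metabolite_t2_star = 0.06,
                                    mm_t2_star = 0.010,
                                    include_mm = TRUE) {
  t2 <- metabolite_t2_star
  tab <- list(
    NAA  = resonance(c(2.008, 2.49, 2.67), c(3.0, 0.8, 0.8), t2),
    tCr  = resonance(c(3.027, 3.913),      c(3.0, 2.0),      t2),
    tCho = resonance(c(3.208, 3.54),       c(9.0, 2.0),      t2),
    Glu  = resonance(c(2.04, 2.12, 2.35, 3.75), c(1, 1, 2, 1), t2),
    Gln  = resonance(c(2.13, 2.45, 3.77),  c(1, 2, 1),       t2),
    mIns = resonance(c(3.27, 3.52, 3.61, 4.05), c(1, 2, 2, 1), t2),
    NAAG = resonance(2.04, 3.0, t2)
  )
  if (include_mm) {
    tab$MM <- resonance(
      c(0.91, 1.21, 1.43, 1.72, 2.05, 2.29, 3.00, 3.21, 3.80),
      c(2.0, 1.5, 1.0, 1.0, 1.5, 1.2, 1.0, 1.0, 1.0),
      mm_t2_star)
  }
  tab
}

#' Simulate the FID of one compound
#'
#' Each resonance k at chemical shift s_k contributes
#' `a_k * exp(1i*2*pi*f_k*(t + delay)) * exp(-(t + delay)/T2*_k)` with
#' `f_k = (s_k - carrier_ppm) * ref_freq_mhz` in Hz, sampled at
#' `t = n / bandwidth` for `n = 0 .. N-1`, `N = round(bandwidth * readout)`.
#' The first stored sample thus sits at physical time `delay` after
#' excitation: the acquisition-delay first-order phase and the initial decay
#' are part of the model, not applied by shifting samples.
#'
#' @param resonances data.frame of resonances (rows from [resonance()]).
#' @param bandwidth_hz sampling bandwidth in Hz.
#' @param readout_s readout duration in seconds.
#' @param delay_s acquisition delay in seconds.
#' @param ref_freq_mhz reference frequency in MHz.
#' @param carrier_ppm carrier position in ppm.
#' @return Complex vector of length `round(bandwidth_hz * readout_s)`.
#' @export
simulate_compound_fid <- function(resonances, bandwidth_hz, readout_s,
                                  delay_s = 0, ref_freq_mhz = 297.2,
                                  carrier_ppm = 4.7) {
  if (is.null(resonances) || nrow(resonances) == 0)
    stop("resonance list is empty")
  if (any(resonances$t2_star <= 0)) stop("t2_star must be > 0")
  stopifnot(bandwidth_hz > 0, readout_s > 0, ref_freq_mhz > 0, delay_s >= 0)
  n <- as.integer(round(bandwidth_hz * readout_s))
  t_eff <- seq_len(n) - 1
  t_eff <- t_eff / bandwidth_hz + delay_s
  fid <- complex(length.out = n)
  for (k in seq_len(nrow(resonances))) {
    f_k <- (resonances$chemical_shift[k] - carrier_ppm) * ref_freq_mhz
    fid <- fid + resonances$relative_amplitude[k] *
      exp((2i * pi * f_k - 1 / resonances$t2_star[k]) * t_eff)
  }
  fid
}

#' Build a basis set of simulated compound signals
#'
#' Simulates one complex time-domain signal per compound of a resonance
#' table under a common acquisition parameter set. All compounds share the
#' number of points, bandwidth, delay and ppm axis.
#'
#' @param compound_table named list mapping compound name to a resonance
#'   data.frame, e.g. from [default_resonance_table()].
#' @param acq an `mrsi_acq` acquisition parameter set.
#' @return An object of class `basis_set` with elements `compound_names`,
#'   `signals` (complex matrix, n_points x n_compounds), `resonances`,
#'   `ppm_axis` and the acquisition constants.
#' @export
build_basis_set <- function(compound_table, acq) {
  stopifnot(inherits(acq, "mrsi_acq"))
  if (length(compound_table) == 0) stop("compound table is empty")
  nms <- names(compound_table)
  if (is.null(nms) || any(nms == "")) stop("all compounds must be named")
  if (anyDuplicated(nms)) stop("duplicate compound names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sig <- vapply(compound_table, function(res) {
    simulate_compound_fid(res, acq$bandwidth_hz, acq$readout_s, acq$delay_s,
                          acq$ref_freq_mhz, acq$carrier_ppm)
  }, complex(acq$n_points))
  sig <- matrix(sig, nrow = acq$n_points, ncol = length(nms),
                dimnames = list(NULL, nms))
  structure(list(
    compound_names = nms,
    signals = sig,
    resonances = compound_table,
    sampling_bandwidth = acq$bandwidth_hz,
    n_points = acq$n_points,
    acquisition_delay = acq$delay_s,
    reference_frequency = acq$ref_freq_mhz,
    carrier_ppm = acq$carrier_ppm,
    ppm_axis = spectral_ppm_axis(acq$n_points, acq$bandwidth_hz,
                                 acq$ref_freq_mhz, acq$carrier_ppm)
  ), class = "basis_set")
}

#' ppm axis of the discrete spectrum
#'
#' Frequency axis of the centred (fftshifted) DFT, converted to ppm via
#' `ppm = carrier_ppm + f / ref_freq_mhz`. Monotone increasing.
#'
#' @param n number of points.
#' @param bandwidth_hz sampling bandwidth in Hz.
#' @param ref_freq_mhz reference frequency in MHz.
#' @param carrier_ppm carrier position in ppm.
#' @return Numeric vector of length `n`.
#' @export
spectral_ppm_axis <- function(n, bandwidth_hz, ref_freq_mhz,
                              carrier_ppm = 4.7) {
  f <- (seq_len(n) - 1 - floor(n / 2)) * bandwidth_hz / n
  carrier_ppm + f / ref_freq_mhz
}

#' Fourier transform an FID to a spectrum
#'
#' Centred (fftshifted) unitary DFT: the spectrum is `fft(fid)/sqrt(N)`,
#' reordered so that the carrier sits at the centre bin. With this
#' normalisation time- and frequency-domain energies are equal (Parseval).
#'
#' @param fid complex time-domain signal.
#' @param bandwidth_hz sampling bandwidth in Hz.
#' @param ref_freq_mhz reference frequency in MHz.
#' @param carrier_ppm carrier position in ppm.
#' @return List with `spectrum` (complex) and `ppm` (axis).
#' @export
fid_to_spectrum <- function(fid, bandwidth_hz, ref_freq_mhz,
                            carrier_ppm = 4.7) {
  if (length(fid) == 0) stop("fid is empty")
  n <- length(fid)
  sp <- stats::fft(fid) / sqrt(n)
  sp <- fftshift_vec(sp)
  list(spectrum = sp,
       ppm = spectral_ppm_axis(n, bandwidth_hz, ref_freq_mhz, carrier_ppm))
}

# centre the zero-frequency bin at output index floor(n/2)+1, so output
# position j holds DFT index (j - 1 - floor(n/2)) mod n -- consistent with
# spectral_ppm_axis() for even and odd n
fftshift_vec <- function(x) {
  n <- length(x)
  kf <- seq_len(n) - 1 - floor(n / 2)
  x[(kf %% n) + 1]
}

#' Frequency-domain basis matrix
#'
#' Transforms every compound signal of a basis set with [fid_to_spectrum()].
#'
#' @param basis a `basis_set`.
#' @return Complex matrix (n_points x n_compounds) with the shared ppm axis
#'   as attribute `"ppm"`.
#' @export
basis_spectra <- function(basis) {
  stopifnot(inherits(basis, "basis_set"))
  sp <- apply(basis$signals, 2, function(s)
    stats::fft(s) / sqrt(length(s)))
  sp <- apply(sp, 2, fftshift_vec)
  dimnames(sp) <- list(NULL, basis$compound_names)
  attr(sp, "ppm") <- basis$ppm_axis
  sp
}

#' Lorentzian linewidth of a compound's narrowest line
#'
#' Closed form FWHM in Hz = 1 / (pi * T2*), evaluated on the basis
#' resonance table (smallest-linewidth line of the compound).
#'
#' @param basis a `basis_set`.
#' @param compound compound name.
#' @return FWHM in Hz.
#' @export
basis_linewidth_hz <- function(basis, compound) {
  stopifnot(inherits(basis, "basis_set"))
  res <- basis$resonances[[compound]]
  if (is.null(res)) stop("unknown compound: ", compound)
  1 / (pi * max(res$t2_star))
}

#' Write / read a basis set container
#'
#' The basis container is stored with R's native serialization, preserving
#' the complex signals bit-exactly; [export_resonance_table()] additionally
#' writes the resonance table as plain CSV for interoperability.
#'
#' @param basis a `basis_set`.
#' @param path file path.
#' @return `write_basis` returns `path` invisibly, `read_basis` the
#'   `basis_set`.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "basis_set"))
  saveRDS(basis, path)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  basis <- readRDS(path)
  stopifnot(inherits(basis, "basis_set"))
  basis
}

#' @rdname write_basis
#' @export
export_resonance_table <- function(basis, path) {
  stopifnot(inherits(basis, "basis_set"))
  rows <- do.call(rbind, lapply(names(basis$resonances), function(nm) {
    cbind(compound = nm, basis$resonances[[nm]])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("Basis set: %d compounds, %d pts, bw %g Hz, delay %g ms\n",
              length(x$compound_names), x$n_points, x$sampling_bandwidth,
              1000 * x$acquisition_delay))
  cat("  compounds:", paste(x$compound_names, collapse = ", "), "\n")
  invisible(x)
}
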