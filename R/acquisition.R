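#' Acquisition parameter set for an MRSI scan
#'
#' Bundles the pulse-sequence parameters that the signal model needs: the
#' repetition time and excitation flip angle (which set the steady-state
#' saturation of each compound through its T1), the spectral bandwidth and
#' readout duration (which set the time axis and the number of complex
#' samples), the acquisition delay between excitation and the first sample
#' (which imposes the first-order phase across the spectrum), and the
#' spectrometer reference frequency and carrier position on the ppm axis.
#'
#' The number of stored complex points is `round(bandwidth_hz * readout_s)`.
#'
#' @param tr_ms repetition time in milliseconds.
#' @param flip_deg excitation flip angle in degrees, in (0, 180).
#' @param bandwidth_hz spectral (sampling) bandwidth in Hz.
#' @param readout_s readout duration in seconds.
#' @param delay_s acquisition delay in seconds (time of the first sample
#'   relative to excitation).
#' @param ref_freq_mhz proton reference frequency in MHz (297.2 at 7 T).
#' @param carrier_ppm chemical shift at the centre of the spectral window,
#'   in ppm (4.7, water, by default).
#' @return An object of class `mrsi_acq`.
#' @export
mrsi_acquisition <- function(tr_ms, flip_deg, bandwidth_hz, readout_s,
                             delay_s = 0.0013, ref_freq_mhz = 297.2,
                             carrier_ppm = 4.7) {
  stopifnot(tr_ms > 0, flip_deg > 0, flip_deg < 180,
            bandwidth_hz > 0, readout_s > 0, delay_s >= 0, ref_freq_mhz > 0)
  structure(list(
    tr_ms = tr_ms, flip_deg = flip_deg, bandwidth_hz = bandwidth_hz,
    readout_s = readout_s, delay_s = delay_s, ref_freq_mhz = ref_freq_mhz,
    carrier_ppm = carrier_ppm,
    n_points = as.integer(round(bandwidth_hz * readout_s))
  ), class = "mrsi_acq")
}

#' Default water-suppressed metabolite-scan acquisition (7 T FID-MRSI)
#'
#' TR 450 ms, 39 degree flip, 2778 Hz bandwidth, 345 ms readout, 1.3 ms
#' acquisition delay.
#' @inheritParams mrsi_acquisition
#' @return An `mrsi_acq` object.
#' @export
metabolite_acquisition <- function(ref_freq_mhz = 297.2, carrier_ppm = 4.7) {
  mrsi_acquisition(tr_ms = 450, flip_deg = 39, bandwidth_hz = 2778,
                   readout_s = 0.345, delay_s = 0.0013,
                   ref_freq_mhz = ref_freq_mhz, carrier_ppm = carrier_ppm)
}

#' Default unsuppressed water-reference acquisition
#'
#' TR 200 ms, 27 degree flip (the Ernst angle for tissue water at this TR),
#' 606 Hz bandwidth, 158 ms readout.
#' @inheritParams mrsi_acquisition
#' @return An `mrsi_acq` object.
#' @export
water_acquisition <- function(ref_freq_mhz = 297.2, carrier_ppm = 4.7) {
  mrsi_acquisition(tr_ms = 200, flip_deg = 27, bandwidth_hz = 606,
                   readout_s = 0.158, delay_s = 0.0013,
                   ref_freq_mhz = ref_freq_mhz, carrier_ppm = carrier_ppm)
}

#' Nominal in-plane voxel size of a Cartesian-matrix acquisition
#'
#' @param fov_mm field of view in mm.
#' @param matrix_size number of points across the field of view.
#' @return Voxel size in mm.
#' @export
nominal_voxel_size <- function(fov_mm, matrix_size) {
  stopifnot(fov_mm > 0, matrix_size >= 1)
  fov_mm / matrix_size
}

#' @export
print.mrsi_acq <- function(x, ...) {
  cat(sprintf(
    "MRSI acquisition: TR %g ms, flip %g deg, bw %g Hz, readout %g s (%d pts), delay %g ms\n",
    x$tr_ms, x$flip_deg, x$bandwidth_hz, x$readout_s, x$n_points,
    1000 * x$delay_s))
  invisible(x)
}
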