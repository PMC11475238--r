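# Shared fixtures, built in code at load time. Kept deliberately small so
# the full suite stays fast; heavier cohort runs live in the acceptance
# tests.

# fast acquisition for fitter unit tests: short readout, 3 well-separated
# singlets plus a broad background line
tiny_acquisition <- function() {
  mrsi_acquisition(tr_ms = 450, flip_deg = 39, bandwidth_hz = 2778,
                   readout_s = 0.1152, delay_s = 0.0013)
}

tiny_resonance_table <- function() {
  list(
    NAA = resonance(2.008, 3, 0.06),
    tCr = resonance(3.027, 3, 0.06),
    tCho = resonance(3.208, 9, 0.06),
    MM = resonance(c(0.95, 2.3, 3.0), c(2, 1, 1), 0.010)
  )
}

tiny_basis <- function() build_basis_set(tiny_resonance_table(),
                                         tiny_acquisition())

# default full-resolution basis, built once
full_basis <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- build_basis_set(default_resonance_table(),
                                          metabolite_acquisition())
    b
  }
})

small_phantom <- local({
  p <- NULL
  function() {
    if (is.null(p)) {
      ph <- build_phantom(c(16, 16, 8))
      p <<- assign_truth_concentrations(ph, n_subjects = 3, seed = 11)
    }
    p
  }
})

# synthetic spectrum from known amplitudes under known nuisance parameters
make_mixture_spectrum <- function(basis, amplitudes, shift_hz = 0,
                                  damp_hz = 0, phase = 0) {
  t_eff <- (seq_len(basis$n_points) - 1) / basis$sampling_bandwidth +
    basis$acquisition_delay
  fid <- as.vector(basis$signals %*% amplitudes) *
    exp((2i * pi * shift_hz - pi * damp_hz) * t_eff) * exp(1i * phase)
  fid_to_spectrum(fid, basis$sampling_bandwidth, basis$reference_frequency,
                  basis$carrier_ppm)$spectrum
}
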