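#' Spectral evaluation ranges
#'
#' The fit objective only uses points inside these closed ppm intervals.
#' The defaults exclude the lipid band (1.2-1.8 ppm, possibly contaminated
#' even after L2 removal) and everything above 3.88 ppm (water-suppression
#' effects): 0.2-1.2 ppm and 1.8-3.88 ppm.
#'
#' @param intervals list of `c(lo, hi)` ppm intervals; must be disjoint.
#' @return An object of class `evaluation_ranges`.
#' @export
evaluation_ranges <- function(intervals = list(c(0.2, 1.2), c(1.8, 3.88))) {
  stopifnot(length(intervals) >= 1)
  for (iv in intervals) stopifnot(length(iv) == 2, iv[1] < iv[2])
  ord <- order(vapply(intervals, `[`, numeric(1), 1))
  ivs <- intervals[ord]
  if (length(ivs) > 1)
    for (i in seq_len(length(ivs) - 1))
      if (ivs[[i]][2] > ivs[[i + 1]][1]) stop("intervals overlap")
  structure(list(intervals = ivs), class = "evaluation_ranges")
}

#' Logical mask of axis points inside the evaluation ranges
#'
#' Closed intervals: boundary points are included.
#' @param ppm ppm axis.
#' @param ranges an `evaluation_ranges`.
#' @return Logical vector.
#' @export
range_mask <- function(ppm, ranges) {
  stopifnot(inherits(ranges, "evaluation_ranges"))
  sel <- rep(FALSE, length(ppm))
  for (iv in ranges$intervals) sel <- sel | (ppm >= iv[1] & ppm <= iv[2])
  sel
}

#' Fitter control settings
#'
#' @param shift_starts starting values for the global frequency shift, Hz
#'   (one optimisation run per start; ties broken by lowest residual, then
#'   lowest shift magnitude).
#' @param damp_start starting extra damping, Hz.
#' @param shift_bound bound on |shift|, Hz.
#' @param damp_bound upper bound on extra damping, Hz.
#' @param maxit maximum optimiser iterations per start.
#' @return List of control settings.
#' @export
fit_control <- function(shift_starts = c(-8, 0, 8), damp_start = 8,
                        shift_bound = 20, damp_bound = 60, maxit = 300) {
  list(shift_starts = shift_starts, damp_start = damp_start,
       shift_bound = shift_bound, damp_bound = damp_bound, maxit = maxit)
}

# modulated frequency-domain basis: each compound FID multiplied by
# exp((2i*pi*shift - pi*damp)(t + delay)), then centred unitary DFT
modulated_basis_spectra <- function(basis, shift_hz, damp_hz) {
  t_eff <- (seq_len(basis$n_points) - 1) / basis$sampling_bandwidth +
    basis$acquisition_delay
  mod <- exp((2i * pi * shift_hz - pi * damp_hz) * t_eff)
  sig <- basis$signals * mod
  sp <- stats::mvfft(sig) / sqrt(basis$n_points)
  n <- basis$n_points
  kf <- seq_len(n) - 1 - floor(n / 2)
  sp[(kf %% n) + 1, , drop = FALSE]
}

# Precomputed closed-form evaluator of the modulated basis on the masked
# bins. Every basis line is a sampled complex exponential
# a * exp(z (t + delay)), z = 2i*pi*(f + shift) - (1/T2* + pi*damp), whose
# centred unitary DFT at bin k is the geometric sum
# a * e^(z*delay) * (1 - e^(z*N/bw)) / (sqrt(N) * (1 - e^(z/bw) * w_k)),
# w_k = exp(-2i*pi*kf/N). This avoids an FFT per objective evaluation.
masked_model_precompute <- function(basis, mask) {
  n <- basis$n_points
  kf <- seq_len(n) - 1 - floor(n / 2)
  rows <- do.call(rbind, lapply(seq_along(basis$resonances), function(j) {
    r <- basis$resonances[[j]]
    data.frame(compound = j,
               f = (r$chemical_shift - basis$carrier_ppm) *
                 basis$reference_frequency,
               g = 1 / r$t2_star, a = r$relative_amplitude)
  }))
  list(res = rows, w = exp(-2i * pi * kf[mask] / n), n = n,
       bw = basis$sampling_bandwidth, tau = basis$acquisition_delay,
       m = length(basis$compound_names), n_masked = sum(mask))
}

masked_basis_matrix <- function(pre, shift_hz, damp_hz, derivs = FALSE) {
  B <- matrix(0i, pre$n_masked, pre$m)
  if (derivs) dBdz <- B
  z <- 2i * pi * (pre$res$f + shift_hz) - (pre$res$g + pi * damp_hz)
  e_n <- exp(z * pre$n / pre$bw)
  e_1 <- exp(z / pre$bw)
  num <- pre$res$a * exp(z * pre$tau) * (1 - e_n) / sqrt(pre$n)
  for (j in seq_len(nrow(pre$res))) {
    den <- 1 - e_1[j] * pre$w
    term <- num[j] / den
    B[, pre$res$compound[j]] <- B[, pre$res$compound[j]] + term
    if (derivs) {
      # d/dz log(term) = tau - (N/bw) e_n/(1-e_n) + (1/bw) e_1 w/(1-e_1 w)
      dlog <- pre$tau - (pre$n / pre$bw) * e_n[j] / (1 - e_n[j]) +
        (1 / pre$bw) * e_1[j] * pre$w / den
      dBdz[, pre$res$compound[j]] <- dBdz[, pre$res$compound[j]] +
        term * dlog
    }
  }
  if (derivs) list(B = B, dBdz = dBdz) else B
}

#' Linear-combination model fit of one spectrum
#'
#' Fits the masked complex spectrum with a non-negative linear combination
#' of the basis compounds under three global nuisance parameters: a
#' frequency shift (|shift| <= 20 Hz), an extra Lorentzian damping
#' (>= 0, added linewidth in Hz) and a zero-order phase (|phase| <= pi).
#' The solve is separable: for each candidate nuisance vector the
#' amplitudes come from a non-negative least-squares solve on the stacked
#' real/imaginary parts of the in-range points; the nuisance vector is
#' optimised by bounded quasi-Newton search with multiple shift starts.
#' Only points inside the evaluation ranges contribute to the objective.
#'
#' @param spectrum complex spectrum on the basis ppm axis.
#' @param basis a `basis_set`.
#' @param ranges an `evaluation_ranges`.
#' @param noise_sd known spectral noise SD per real/imaginary component, or
#'   `NULL` to estimate it from the fit residual.
#' @param control from [fit_control()].
#' @return An object of class `fit_result`: non-negative `amplitudes`,
#'   `crlb_percent`, `global_shift_hz`, `extra_damping_hz`,
#'   `zero_order_phase`, `snr` (if tCr is in the basis and noise is known),
#'   `fwhm_ppm`, `fit_residual`, `converged`.
#' @export
fit_spectrum <- function(spectrum, basis, ranges = evaluation_ranges(),
                         noise_sd = NULL, control = fit_control()) {
  stopifnot(inherits(basis, "basis_set"))
  if (length(spectrum) != basis$n_points)
    stop("spectrum and basis do not share an axis")
  if (any(!is.finite(Re(spectrum))) || any(!is.finite(Im(spectrum))))
    stop("non-finite values in spectrum")
  mask <- range_mask(basis$ppm_axis, ranges)
  s_m <- spectrum[mask]
  y2 <- sum(Mod(s_m)^2)
  m <- length(basis$compound_names)
  pre <- masked_model_precompute(basis, mask)

  # separable solve: amplitudes by NNLS on the normal equations
  # (G = Re(B^H B) is phase-invariant), objective and its analytic
  # gradient in (shift, damp, phase) at the NNLS optimum (envelope
  # theorem: da/dtheta terms vanish)
  cache <- new.env(parent = emptyenv())
  nnls_at <- function(par) {
    if (identical(cache$par, par)) return(cache$sol)
    mb <- masked_basis_matrix(pre, par[1], par[2], derivs = TRUE)
    B <- mb$B
    Bh <- Conj(t(B))
    G <- Re(Bh %*% B)
    bb <- Re(exp(-1i * par[3]) * (Bh %*% s_m))
    R <- tryCatch(chol(G + diag(1e-10 * max(diag(G)), m)),
                  error = function(e) NULL)
    if (is.null(R)) {                      # degenerate basis: direct solve
      C <- rbind(Re(B * exp(1i * par[3])), Im(B * exp(1i * par[3])))
      a <- pracma::lsqnonneg(C, c(Re(s_m), Im(s_m)))$x
    } else {
      d <- as.vector(backsolve(R, bb, transpose = TRUE))
      a <- pracma::lsqnonneg(R, d)$x
    }
    resid2 <- max(y2 - 2 * sum(bb * a) + sum(a * (G %*% a)), 0)
    sol <- list(a = a, resid2 = resid2, B = B * exp(1i * par[3]),
                dBdz = mb$dBdz)
    cache$par <- par; cache$sol <- sol
    sol
  }
  obj <- function(par) nnls_at(par)$resid2
  grad <- function(par) {
    sol <- nnls_at(par)
    model <- as.vector(sol$B %*% sol$a)
    r <- s_m - model
    dmdz <- exp(1i * par[3]) * as.vector(sol$dBdz %*% sol$a)
    g <- function(dm) -2 * sum(Re(Conj(r) * dm))
    c(g(2i * pi * dmdz), g(-pi * dmdz), g(1i * model))
  }

  lower <- c(-control$shift_bound, 0, -pi)
  upper <- c(control$shift_bound, control$damp_bound, pi)
  runs <- lapply(control$shift_starts, function(s0) {
    stats::optim(c(s0, control$damp_start, 0), obj, grad,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = control$maxit, factr = 1e7))
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  shifts <- vapply(runs, function(r) abs(r$par[1]), numeric(1))
  best <- order(vals, shifts)[1]
  run <- runs[[best]]
  # Newton polish: the optimum must be located far more precisely than the
  # quasi-Newton stopping ball, so that amplitude estimates are exactly
  # invariant to a global receiver gain (analytic gradient, 3x3
  # finite-difference Hessian, quadratic convergence from the search
  # solution)
  par <- run$par
  h_fd <- c(1e-4, 1e-4, 1e-6)
  g <- grad(par)
  for (it in 1:12) {
    H <- matrix(0, 3, 3)
    for (j in 1:3) {
      e <- c(0, 0, 0); e[j] <- h_fd[j]
      H[, j] <- (grad(par + e) - grad(par - e)) / (2 * h_fd[j])
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- pmin(pmax(par - step, lower), upper)
    g_cand <- grad(cand)
    # gradient-norm control: near the optimum objective differences are
    # cancellation noise and cannot steer the iteration
    if (sum(abs(g_cand)) >= sum(abs(g))) break
    moved <- sum(abs(cand - par))
    par <- cand; g <- g_cand
    if (moved < 1e-14 * (1 + sum(abs(par)))) break
  }
  if (obj(par) <= run$value + 1e-9 * y2) run$par <- par
  sol <- nnls_at(run$par)
  # final amplitudes through the QR-based solver on the stacked system:
  # the normal-equations shortcut used inside the search squares the
  # condition number of overlapping compounds (e.g. NAA/NAAG)
  Cfin <- rbind(Re(sol$B), Im(sol$B))
  sol$a <- pracma::lsqnonneg(Cfin, c(Re(s_m), Im(s_m)))$x
  a <- as.vector(sol$a); names(a) <- basis$compound_names
  sol$resid2 <- sum((c(Re(s_m), Im(s_m)) - Cfin %*% a)^2)

  fitted <- as.vector(sol$B %*% a)
  resid <- spectrum[mask] - fitted
  sd_used <- if (!is.null(noise_sd) && noise_sd > 0) noise_sd else {
    # unknown (or zero) noise: estimate from the fit residual, with a
    # floor so noiseless data keeps a finite Fisher matrix
    max(stats::sd(c(Re(resid), Im(resid))), 1e-12)
  }

  J <- fit_jacobian(basis, mask, run$par, a)
  crlb <- crlb_percent(J, sd_used, a)

  damp_at_bound <- run$par[2] >= control$damp_bound - 1e-6
  fwhm_ppm <- if ("tCr" %in% basis$compound_names) {
    (basis_linewidth_hz(basis, "tCr") + run$par[2]) /
      basis$reference_frequency
  } else NA_real_

  res <- structure(list(
    amplitudes = a, crlb_percent = crlb,
    global_shift_hz = run$par[1], extra_damping_hz = run$par[2],
    zero_order_phase = run$par[3],
    fwhm_ppm = fwhm_ppm, damping_at_bound = damp_at_bound,
    fit_residual = resid, resid2 = sol$resid2,
    noise_sd = sd_used, mask = mask,
    converged = run$convergence == 0,
    basis_compounds = basis$compound_names
  ), class = "fit_result")
  res$snr <- if ("tCr" %in% basis$compound_names && sd_used > 0)
    estimate_snr(res, basis, noise_sd = sd_used) else NA_real_
  res
}

# complex Jacobian of the masked model at the optimum, columns:
# amplitudes (m), shift, damping, phase
fit_jacobian <- function(basis, mask, par, a) {
  t_eff <- (seq_len(basis$n_points) - 1) / basis$sampling_bandwidth +
    basis$acquisition_delay
  mod <- exp((2i * pi * par[1] - pi * par[2]) * t_eff)
  u <- function(x) {   # unitary centred DFT
    n <- length(x)
    fftshift_vec(stats::fft(x) / sqrt(n))
  }
  ph <- exp(1i * par[3])
  Bcols <- lapply(seq_along(a), function(j)
    ph * u(basis$signals[, j] * mod)[mask])
  model_fid <- as.vector(basis$signals %*% a) * mod
  d_shift <- ph * u(model_fid * (2i * pi * t_eff))[mask]
  d_damp <- ph * u(model_fid * (-pi * t_eff))[mask]
  d_phase <- 1i * ph * u(model_fid)[mask]
  J <- cbind(do.call(cbind, Bcols), d_shift, d_damp, d_phase)
  colnames(J) <- c(names(a), ".shift", ".damp", ".phase")
  J
}

#' Cramer-Rao lower bounds in percent of the fitted amplitudes
#'
#' `CRLB_m = 100 * sqrt([F^-1]_mm) / A_m` with the Fisher matrix
#' `F = Re(J^H J) / sigma^2` for complex Gaussian noise of standard
#' deviation `sigma` per real/imaginary component. Compounds with
#' (near-)zero amplitude get an infinite CRLB; a singular Fisher matrix is
#' handled by pseudo-inversion and the affected compounds are flagged with
#' infinite CRLBs.
#'
#' @param jacobian complex Jacobian at the optimum (points x parameters);
#'   the first `length(amplitudes)` columns must be the amplitude
#'   derivatives.
#' @param noise_sd noise SD per component, > 0.
#' @param amplitudes fitted amplitudes.
#' @param eps amplitude below which the CRLB is reported as infinite.
#' @return Named vector of CRLB percentages.
#' @export
crlb_percent <- function(jacobian, noise_sd, amplitudes, eps = 1e-9) {
  stopifnot(noise_sd > 0)
  Fm <- Re(Conj(t(jacobian)) %*% jacobian) / noise_sd^2
  cv <- tryCatch(solve(Fm), error = function(e) NULL)
  singular <- is.null(cv)
  if (singular) cv <- pracma::pinv(Fm)
  m <- length(amplitudes)
  v <- diag(cv)[seq_len(m)]
  out <- 100 * sqrt(pmax(v, 0)) / amplitudes
  out[amplitudes <= eps] <- Inf
  if (singular) out[v <= 0] <- Inf
  names(out) <- names(amplitudes)
  out
}

#' Spectral SNR of the tCr fit
#'
#' SNR is the height of the phased (real-part) fitted tCr resonance at
#' 3.02 ppm divided by the spectral noise SD. The noise SD can be supplied
#' (synthetic mode, known generator noise), estimated from a signal-free
#' ppm region of a measured spectrum, or estimated by the pseudo-replica
#' method from noise-only prescan FIDs pushed through the same transform
#' as the data.
#'
#' @param fit a `fit_result`.
#' @param basis the `basis_set` used for the fit.
#' @param noise_sd known spectral noise SD (method `"known"`).
#' @param method noise source.
#' @param spectrum complex spectrum (needed for `"region"`).
#' @param region signal-free ppm interval for `"region"`.
#' @param prescans complex matrix of noise-only FIDs (for
#'   `"pseudo_replica"`).
#' @param n_replicas number of pseudo-replica resamples.
#' @return SNR (dimensionless).
#' @export
estimate_snr <- function(fit, basis, noise_sd = NULL,
                         method = c("known", "region", "pseudo_replica"),
                         spectrum = NULL, region = c(8.5, 9.3),
                         prescans = NULL, n_replicas = 100) {
  method <- match.arg(method)
  sd_est <- switch(method,
    known = {
      if (is.null(noise_sd)) stop("noise_sd required for method 'known'")
      noise_sd
    },
    region = {
      if (is.null(spectrum)) stop("spectrum required for method 'region'")
      sel <- basis$ppm_axis >= region[1] & basis$ppm_axis <= region[2]
      if (!any(sel)) stop("noise region outside the ppm axis")
      stats::sd(Re(spectrum[sel]))
    },
    pseudo_replica = pseudo_replica_noise_sd(prescans, n_replicas)
  )
  if (!is.finite(sd_est) || sd_est <= 0) stop("zero noise estimate: SNR undefined")
  peak <- fitted_tcr_peak_height(fit, basis)
  peak / sd_est
}

# phased real-part height of the fitted tCr line near 3.02 ppm
fitted_tcr_peak_height <- function(fit, basis) {
  if (!"tCr" %in% basis$compound_names) stop("no tCr compound in basis")
  B <- modulated_basis_spectra(basis, fit$global_shift_hz,
                               fit$extra_damping_hz)
  tcr <- B[, "tCr"] * fit$amplitudes["tCr"]
  near <- abs(basis$ppm_axis - 3.027 - fit$global_shift_hz /
                basis$reference_frequency) < 0.15
  ph <- Arg(tcr[near][which.max(Mod(tcr[near]))])
  max(Re(tcr[near] * exp(-1i * ph)))
}

#' Pseudo-replica noise estimate
#'
#' Pushes noise-only prescan FIDs (optionally resampled to `n_replicas`
#' replicas) through the same unitary DFT as the data and returns the
#' spectral noise SD per real/imaginary component.
#'
#' @param prescans complex matrix, points x prescan FIDs.
#' @param n_replicas number of replicas to draw (with replacement across
#'   prescans, sign-randomised) when more replicas than prescans are
#'   requested.
#' @param seed seed for the resampling.
#' @return Estimated spectral noise SD.
#' @export
pseudo_replica_noise_sd <- function(prescans, n_replicas = 100, seed = 1L) {
  if (is.null(prescans) || ncol(prescans) == 0)
    stop("prescans required for the pseudo-replica method")
  n <- nrow(prescans)
  set.seed(as.integer(seed))
  reps <- matrix(0i, n, n_replicas)
  for (r in seq_len(n_replicas)) {
    j <- sample.int(ncol(prescans), 1)
    sgn <- sample(c(-1, 1), 1)
    perm <- sample.int(n)
    reps[, r] <- sgn * prescans[perm, j]
  }
  sp <- stats::mvfft(reps) / sqrt(n)
  stats::sd(c(Re(sp), Im(sp)))
}

#' Linewidth of the tCr fit
#'
#' `FWHM_Hz = 1/(pi * T2*_tCr) + extra damping`, converted to ppm by the
#' reference frequency. The basis linewidth and the fitted extra damping
#' are both Lorentzian, so their widths add.
#'
#' @param fit a `fit_result`.
#' @param basis the `basis_set` used for the fit.
#' @return FWHM in ppm, with attribute `"flagged"` when the damping
#'   estimate sits at its bound.
#' @export
estimate_fwhm <- function(fit, basis) {
  if (!"tCr" %in% basis$compound_names) stop("no tCr compound in basis")
  out <- (basis_linewidth_hz(basis, "tCr") + fit$extra_damping_hz) /
    basis$reference_frequency
  if (isTRUE(fit$damping_at_bound)) attr(out, "flagged") <- "damping at bound"
  out
}

#' Fit the unsuppressed water-reference spectrum of one voxel
#'
#' Single-resonance fit at ~4.7 ppm: a complex amplitude (magnitude +
#' phase) is solved linearly for each candidate (shift, damping) pair,
#' which are optimised by bounded search. Voxels whose fitted peak does not
#' rise above the noise are flagged instead of silently passed on.
#'
#' @param water_spectrum complex spectrum on the water-basis axis.
#' @param water_basis single-compound `basis_set` from
#'   [build_water_basis()].
#' @param noise_sd optional spectral noise SD used for the above-noise
#'   check.
#' @param control from [fit_control()] (shift starts reused).
#' @return List with `amplitude` (>= 0), `shift_hz`, `extra_damping_hz`,
#'   `phase`, `linewidth_hz`, `flagged`.
#' @export
fit_water <- function(water_spectrum, water_basis, noise_sd = NULL,
                      control = fit_control()) {
  stopifnot(inherits(water_basis, "basis_set"),
            length(water_spectrum) == water_basis$n_points)
  pre <- masked_model_precompute(water_basis,
                                 rep(TRUE, water_basis$n_points))
  s <- water_spectrum
  y2 <- sum(Mod(s)^2)
  solve_c <- function(par) {
    mb <- masked_basis_matrix(pre, par[1], par[2], derivs = TRUE)
    b <- mb$B[, 1]
    n2 <- sum(Mod(b)^2)
    u <- sum(Conj(b) * s)
    cc <- u / n2
    list(c = cc, resid2 = max(y2 - Mod(u)^2 / n2, 0), b = b,
         db = mb$dBdz[, 1], u = u, n2 = n2)
  }
  obj <- function(par) solve_c(par)$resid2
  grad <- function(par) {
    w <- solve_c(par)
    vapply(list(2i * pi * w$db, -pi * w$db), function(db) {
      du <- sum(Conj(db) * s)
      dn2 <- 2 * Re(sum(Conj(w$b) * db))
      -(2 * Re(Conj(w$u) * du) * w$n2 - Mod(w$u)^2 * dn2) / w$n2^2
    }, numeric(1))
  }
  lower <- c(-control$shift_bound, 0)
  upper <- c(control$shift_bound, control$damp_bound)
  runs <- lapply(control$shift_starts, function(s0)
    stats::optim(c(s0, control$damp_start), obj, grad, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = control$maxit, factr = 1e4)))
  vals <- vapply(runs, `[[`, numeric(1), "value")
  run <- runs[[order(vals, vapply(runs, function(r) abs(r$par[1]),
                                  numeric(1)))[1]]]
  # Newton polish (see fit_spectrum): locate the optimum to machine
  # precision for exact receiver-gain invariance. Iteration control is on
  # the gradient norm: near the optimum the objective itself is dominated
  # by cancellation noise (residual << total energy) and cannot be
  # compared reliably.
  par <- run$par
  h_fd <- c(1e-5, 1e-5)
  g <- grad(par)
  for (it in 1:12) {
    H <- matrix(0, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h_fd[j]
      H[, j] <- (grad(par + e) - grad(par - e)) / (2 * h_fd[j])
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- pmin(pmax(par - step, lower), upper)
    g_cand <- grad(cand)
    if (sum(abs(g_cand)) >= sum(abs(g))) break
    moved <- sum(abs(cand - par))
    par <- cand; g <- g_cand
    if (moved < 1e-13 * (1 + sum(abs(par)))) break
  }
  if (obj(par) <= run$value + 1e-9 * y2) run$par <- par
  sol <- solve_c(run$par)
  amp <- Mod(sol$c)
  lw <- basis_linewidth_hz(water_basis, water_basis$compound_names[1]) +
    run$par[2]
  peak <- amp * max(Mod(sol$b))
  flagged <- if (!is.null(noise_sd) && noise_sd > 0) peak < 3 * noise_sd
  else amp == 0
  list(amplitude = amp, shift_hz = run$par[1],
       extra_damping_hz = run$par[2], phase = Arg(sol$c),
       linewidth_hz = lw, flagged = flagged)
}

#' Fit every selected voxel of a subject dataset
#'
#' Convenience loop: transforms the stored FIDs, optionally applies L2
#' lipid removal, fits the metabolite spectra and the water spectra, and
#' returns per-voxel tables and map vectors.
#'
#' @param dataset a `subject_dataset`.
#' @param basis metabolite `basis_set`.
#' @param water_basis water `basis_set`.
#' @param voxels indices into the dataset's voxel set to fit (default: all
#'   brain voxels).
#' @param lipid_removal apply L2 lipid removal before fitting.
#' @param lipid_beta `"auto"` or a numeric weight.
#' @param ranges evaluation ranges.
#' @param control fitter control.
#' @return List with `table` (data.frame of per-voxel scalars),
#'   `amplitudes` and `crlb` matrices (voxel x compound), `water`
#'   (data.frame), `voxel_index` (3D linear indices of the fitted voxels)
#'   and `lipid_beta`.
#' @export
fit_dataset <- function(dataset, basis, water_basis, voxels = NULL,
                        lipid_removal = TRUE, lipid_beta = "auto",
                        ranges = evaluation_ranges(),
                        control = fit_control()) {
  sp <- subject_spectra(dataset, "metabolite")
  wsp <- subject_spectra(dataset, "water")
  in_brain <- dataset$brain_mask[dataset$voxel_index]
  if (is.null(voxels)) voxels <- which(in_brain)
  spectra <- sp$spectra
  beta_used <- 0
  if (lipid_removal) {
    lb <- extract_lipid_basis(dataset, n_components = 8)
    beta_used <- if (identical(lipid_beta, "auto"))
      auto_lipid_beta(spectra[, voxels, drop = FALSE], lb) else lipid_beta
    spectra <- l2_lipid_removal(spectra, lb, beta_used)
  }
  m <- length(basis$compound_names)
  nv <- length(voxels)
  amps <- matrix(NA_real_, nv, m, dimnames = list(NULL, basis$compound_names))
  crlbs <- amps
  tab <- data.frame(voxel = dataset$voxel_index[voxels],
                    snr = NA_real_, fwhm_ppm = NA_real_,
                    shift_hz = NA_real_, damping_hz = NA_real_,
                    phase = NA_real_, converged = NA)
  wtab <- data.frame(voxel = dataset$voxel_index[voxels],
                     amplitude = NA_real_, flagged = NA)
  for (i in seq_len(nv)) {
    v <- voxels[i]
    ft <- fit_spectrum(spectra[, v], basis, ranges,
                       noise_sd = dataset$noise_sd, control = control)
    amps[i, ] <- ft$amplitudes
    crlbs[i, ] <- ft$crlb_percent
    tab$snr[i] <- ft$snr
    tab$fwhm_ppm[i] <- ft$fwhm_ppm
    tab$shift_hz[i] <- ft$global_shift_hz
    tab$damping_hz[i] <- ft$extra_damping_hz
    tab$phase[i] <- ft$zero_order_phase
    tab$converged[i] <- ft$converged
    wf <- fit_water(wsp$spectra[, v], water_basis,
                    noise_sd = dataset$noise_sd, control = control)
    wtab$amplitude[i] <- wf$amplitude
    wtab$flagged[i] <- wf$flagged
  }
  list(table = tab, amplitudes = amps, crlb = crlbs, water = wtab,
       voxel_index = dataset$voxel_index[voxels], lipid_beta = beta_used)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Linear-combination fit:\n")
  print(round(rbind(amplitude = x$amplitudes, crlb_pct = x$crlb_percent), 3))
  cat(sprintf("  shift %.2f Hz, damping %.2f Hz, phase %.3f rad, SNR %.1f, FWHM %.4f ppm\n",
              x$global_shift_hz, x$extra_damping_hz, x$zero_order_phase,
              x$snr, x$fwhm_ppm))
  invisible(x)
}
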