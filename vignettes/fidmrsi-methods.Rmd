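---
title: "Quantification and stability analysis for 7 T FID-MRSI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification and stability analysis for 7 T FID-MRSI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fidmrsi)
```

## Scope

`fidmrsi` implements a complete quantification chain for free-induction-decay
magnetic resonance spectroscopic imaging (FID-MRSI) of the brain at 7 T: a
Lorentzian basis simulator, a synthetic multi-subject phantom generator with
known ground truth, L2-regularised lipid removal, linear-combination spectral
fitting with Cramér–Rao lower bounds (CRLBs), water-referenced absolute
concentration estimation with tissue-fraction and T1 saturation correction,
spectral quality masking, and region-of-interest (ROI) cohort statistics,
including inter-subject coefficients of variation (CVs). The design follows
the acquisition and evaluation protocol of a published whole-brain
concentric-ring-trajectory FID-MRSI volunteer study at 7 T; that study's
per-ROI cohort tables ship with the package as labelled transcriptions
(`load_reference_tables()`) so its printed summary statistics can be
recomputed exactly.

## Signal model

Each compound is a sum of Lorentzian resonances. A resonance at chemical
shift $s_k$ ppm with weight $a_k$ and apparent transverse relaxation
$T_{2,k}^*$ contributes, at sample times $t_n = n/\mathrm{bw}$,

$$x(t_n) = a_k \exp\!\big[(2\pi i f_k - 1/T^*_{2,k})(t_n + \tau)\big],
\qquad f_k = (s_k - s_\mathrm{carrier})\,\nu_0,$$

with $\nu_0 = 297.2$ MHz (proton at 7 T), carrier at 4.7 ppm (water), and
acquisition delay $\tau = 1.3$ ms. The delay is applied inside the model —
the first stored sample sits at physical time $\tau$ — which produces the
characteristic first-order phase across the spectrum rather than a sample
shift. The water-suppressed metabolite scan uses TR 450 ms, 39° flip,
2778 Hz bandwidth and a 345 ms readout (958 complex points); the
unsuppressed water reference uses TR 200 ms, 27° (the Ernst angle of tissue
water at this TR), 606 Hz and 158 ms. Spectra are centred unitary DFTs, so
time- and frequency-domain energies agree (Parseval) and noise standard
deviations carry over unchanged.

The built-in resonance table is a singlet/simple-multiplet approximation
(NAA, tCr, tCho, Glu, Gln, mIns, NAAG), not a density-matrix simulation:
coupled spin systems are represented by a few lines at their main multiplet
positions. This suffices for a generator and fitter that share the same
basis; it does not reproduce J-evolution fine structure of real spectra.
The macromolecular background ("MM") is modelled as nine broad Lorentzians
(T2* ≈ 10 ms) between 0.9 and 3.9 ppm and is included both in the generator
and as a fit compound, absorbing baseline in place of a spline.

## Synthetic phantom cohort

The phantom is an ellipsoidal head on a configurable grid (default
32×32×16; tests and the acceptance script mostly use 16×16×8 to keep
runtimes in minutes — all thresholds are resolution independent). Smooth
radial profiles produce a WM core, a cortical GM shell, a CSF rim plus two
ventricle pockets and an outer scalp ring; per voxel
$f_{GM}+f_{WM}+f_{CSF}+f_{bg}=1$. Six default ROIs cross tissue dominance
with spatial sectors.

Subject-level tissue concentrations are drawn log-normally per compound and
tissue, mean-parameterised so the expectation equals the configured tissue
mean and the coefficient of variation equals `inter_subject_cv` (default
10%, the order of variability the reference cohort exhibits). Draws are
independent across metabolites and tissues; real metabolic profiles are
correlated, so cohort tests validate the statistical machinery, not
biological covariance. Default GM/WM means (mM) were fixed once to sit in
the published healthy-brain ranges with the expected contrasts (Glu higher
in GM, tCho higher in WM): NAA 10.0/9.7, tCr 8.0/7.2, tCho 1.7/2.0,
Glu 9.0/7.0, Gln 3.0/2.0, mIns 5.3/5.2, NAAG 1.0/2.0.

Voxel truth is $f_{GM}C_{GM,s}+f_{WM}C_{WM,s}$; CSF carries water but no
metabolites. The metabolite FID of a voxel scales each compound by its
tissue-weighted Ernst saturation factor at TR 450 ms/39°; the water FID
scales the water basis by
$1000\sum_c f_c W_c E_c$ with compartment water concentrations
$W = 36.1/43.3/53.8$ mol/L (GM/WM/CSF) and compartment Ernst factors at
TR 200 ms/27°. All voxels receive an extra Lorentzian broadening (default
12 Hz, bringing the tCr linewidth to ≈ 0.058 ppm, matching the ≈ 0.06 ppm
a well-shimmed 7 T acquisition shows). Scalp voxels carry a broad lipid
signal (lines at 0.90/1.30/1.60 ppm) that bleeds into peripheral brain
voxels through convolution with the same 5-voxel Hamming point spread used
as the acquisition's apodisation model — bleed phenomenology without
k-space simulation. Complex Gaussian noise is calibrated by default so the
tCr spectral SNR in a deep-WM voxel is ≈ 11 (the cohort-typical value);
noise-only prescan FIDs are stored for the pseudo-replica noise estimator.
Motion-flagged subjects get +38 Hz broadening and a spatial phase ramp,
which reliably drives them past the linewidth threshold of the quality
mask. Water T1 for CSF defaults to 4300 ms: the relaxation table lists
GM/WM values only, and the CSF water compartment needs a long-T1 default.

## Lipid removal

Scalp-voxel spectra span the lipid contamination subspace; collected as
columns of $L$ (optionally SVD-compressed), the removal operator is
$(I + \beta L L^H)^{-1}$, evaluated through the SVD shrinkage form
$s - U\,\mathrm{diag}\!\big(\beta d_i^2/(1+\beta d_i^2)\big)U^H s$, which
is exact and stable for arbitrarily large $\beta$. The operator is linear,
self-adjoint, positive, and never increases the norm; at $\beta = 0$ it is
the identity.

The weight is chosen by bisection on $\log\beta$ until the residual
lipid-band (1.2–1.8 ppm) signal in the supplied brain spectra reaches a
target fraction of its pre-removal value. The fraction is measured on the
RMS amplitude (default 5%), not on energy: residual lipid biases the fit in
proportion to its amplitude (largely by dragging the global shift/phase
nuisance parameters), and a 5% energy target would still leave ≈ 22%
residual amplitude and double-digit NAA bias in heavily contaminated
voxels. When the band is dominated by macromolecular signal outside the
lipid subspace the target may be unreachable; the bisection then returns
its bracket maximum, which amounts to projecting the lipid subspace out —
a safe limit, since metabolite spectra hold under 1% of their energy there.

## Spectral fitting

Each voxel spectrum is fit as a non-negative linear combination of the
basis compounds under three global nuisance parameters: frequency shift
(|shift| ≤ 20 Hz), extra Lorentzian damping (0–60 Hz of added linewidth)
and zero-order phase (|φ| ≤ π), a deliberately lean stand-in for a full
LCModel-style lineshape model. Only points inside the evaluation ranges
0.2–1.2 and 1.8–3.88 ppm (closed intervals) contribute: the lipid band is
excluded even after removal, and everything above 3.88 ppm is compromised
by water suppression.

The solve is separable: amplitudes come from a non-negative least-squares
solve at each candidate nuisance vector (normal-equations form with a
Cholesky factor inside the search — the Gram matrix is phase-invariant —
and one QR-based solve at the final parameters, because the
normal-equations shortcut squares the condition number of overlapping
compounds such as NAA/NAAG). The nuisance search is bounded L-BFGS-B with
an analytic envelope-theorem gradient, three shift starts (−8, 0, +8 Hz;
ties broken by lowest residual, then smallest shift), followed by a Newton
polish (analytic gradient, finite-difference Hessian, gradient-norm
controlled because objective differences near the optimum are cancellation
noise). The polish pins the optimum far inside the search tolerance ball,
which is what makes concentration estimates invariant to a global receiver
gain at the 10⁻¹³ level. The basis under shift/damping modulation is
evaluated in closed form per masked bin (each line is a sampled complex
exponential, so its DFT is a geometric sum), avoiding an FFT per objective
evaluation.

CRLBs use the Fisher matrix $F = \mathrm{Re}(J^H J)/\sigma^2$ over all
parameters at the optimum, reported per compound as
$100\sqrt{[F^{-1}]_{mm}}/A_m$, with ∞ for near-zero amplitudes and
pseudo-inversion with flagging for singular $F$. SNR is the phased
real-part height of the fitted tCr line at 3.02 ppm over the spectral noise
SD — known generator SD in synthetic mode, a signal-free region (default
8.5–9.3 ppm, inside this acquisition's spectral window) for measured data,
or the pseudo-replica estimate from noise prescans. The linewidth is the
closed form $1/(\pi T^*_{2,\mathrm{tCr}})$ plus the fitted damping,
converted to ppm. Water is fit per voxel as a single resonance at 4.7 ppm
with a complex amplitude solved linearly inside a (shift, damping) search;
voxels whose peak stays below 3× the noise are flagged.

## Quantification

Concentrations follow internal water referencing with partial-volume and
T1 saturation correction:

$$C_m = \frac{A_m}{A_w}\; W_\mathrm{voxel}\,
\frac{E_{w,\mathrm{eff}}}{E_{m,\mathrm{eff}}}\,\frac{1}{1-f_{CSF}},$$

where $W_\mathrm{voxel} = f_{GM}36.1+f_{WM}43.3+f_{CSF}53.8$ mol/L
(reported in mM), $E_{w,\mathrm{eff}}$ is the water-content-weighted water
Ernst factor, $E_{m,\mathrm{eff}}$ the GM/WM tissue-fraction-weighted
metabolite Ernst factor from the 7 T T1 table (tCho 1510/1320, tCr
1780/1740, Glu 1610/1750, Gln 1540/1740, mIns 1280/1190, NAA 1535/1545,
NAAG 1210/940, water 2000/1550 ms for GM/WM), and $1/(1-f_{CSF})$ refers
the metabolite signal to the tissue volume, CSF being metabolite-free. No
T2 correction is applied — with a 1.3 ms acquisition delay the T2
weighting is negligible. The metabolite-scan flip angle is taken as
configured (39°), not recomputed from the T1 table. The estimate is
exactly invariant to a common receiver gain and inverts the generator
model, so on noiseless data the voxel estimates reproduce the
tissue-referenced truth to optimizer precision.

The quality mask excludes voxels with tCr SNR < 5, tCr FWHM > 0.15 ppm,
compound CRLB > 40%, or a fit value beyond 13 raw (unscaled) median
absolute deviations; the MAD filter runs per compound per subject over the
fitted brain voxels, and a zero-MAD population with distinct values falls
back to a logged relative-tolerance rule. Per-rule exclusion counts are
reported.

## Cohort statistics

ROI quality is the percentage of ROI voxels where NAA, tCr, tCho and mIns
all have CRLB < 40%: ≥ 80% is *good*, ≥ 66% *acceptable*, below that
*rejected* (rejected ROIs carry no cohort statistics). The printed
protocol leaves a gap between "66–79% acceptable" and "< 60% rejected";
the 66% cut is the resolution consistent with the reference study's own
count of 18 + 26 = 44 retained regions, and it is configurable.
Metabolites are discarded when fit in under 10% of brain voxels and
qualify when their mean per-ROI pass fraction (strictly) exceeds 66%.
Per-subject ROI means are arithmetic means over quality-passing voxels;
cohort tables report the inter-subject mean, SD and CV
($100\cdot\mathrm{SD}/\mathrm{mean}$, sample SD). Ratios to tCr are formed
per subject as ratio of ROI means and then summarised — the alternative
(voxelwise ratios averaged later) is not what the reference tables imply,
as their thalamic ratio matches the ratio-of-means ordering. Report
rounding follows the reference layout: CVs to integers, concentrations to
2 decimals. A subject/ROI exclusion manifest is honoured before averaging,
and subjects whose tCr pass fraction falls below 50% (e.g. simulated
motion) are excluded and listed.

## Numerical choices and degenerate inputs

* Evaluation-range boundaries are included (closed intervals); the upper
  bound is exactly 3.88 ppm.
* NNLS inner solves use `pracma::lsqnonneg`; a failed Cholesky falls back
  to the stacked QR route.
* Zero or unknown noise uses the residual SD with a 10⁻¹² floor so the
  Fisher matrix stays finite on noiseless fixtures.
* Flagging, not silent failure: water voxels without a peak, voxels with
  $f_{CSF}\approx 1$, singular Fisher matrices and damping estimates at
  their bound are all flagged downstream.
* All randomness flows from one root seed through named substreams per
  stage and subject; identical configuration reproduces bit-identical
  outputs.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run, as the package's own
choices: noiseless recovery on 30 voxels of a 16×16×8 phantom;
CRLB calibration with 200 Monte-Carlo replicates of a four-compound
spectrum (single shift start — the replicate study has no frequency
offset); CV recovery on a 20-subject cohort at 10% generated CV with 6
fitted voxels per ROI; the quality-mask oracle on a seeded 32×32×16
fixture; lipid efficacy on the three most contaminated peripheral voxels;
and gain invariance on 5 voxels. On one CPU the whole acceptance script
runs in about two minutes.

## What passing tests do and do not show

The generator and fitter share the basis, so noiseless recovery validates
the estimation chain, not basis realism. Real data add J-coupled
multiplet structure, B0/B1 inhomogeneity, non-Lorentzian lineshapes,
chemical-shift displacement and k-space truncation artefacts that this
phantom deliberately omits (per-voxel frequency offsets and the Hamming
bleed are the only spatial non-idealities modelled). The reference-table
reproduction checks the summary machinery against the published cohort
exactly, but those numbers come from 23 scanned volunteers and are not
re-derivable from synthetic data at desk scale.

## Known limitations

Single global shift/phase/damping per voxel (no per-compound lineshape),
no B0/B1 field correction, no eddy-current model, no spline baseline, no
k-space/coil simulation, and ratio/CV behaviour under correlated
between-metabolite biology is untested by construction.
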