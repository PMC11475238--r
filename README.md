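# fidmrsi

Metabolite quantification and inter-subject stability analysis for
whole-brain FID-MRSI of the human brain at 7 T.

High-resolution free-induction-decay MRSI measures a spectrum in every
voxel of a 3D brain grid. Turning those spectra into absolute metabolite
concentrations — and knowing in which brain regions the estimates are
stable across people — requires a chain of steps that this package
implements as tested, reusable R functions:

1. **Basis simulation** — Lorentzian metabolite, macromolecular, lipid and
   water signals under the acquisition constants (TR 450 ms / 39° and
   2778 Hz / 345 ms for the metabolite scan; TR 200 ms / 27° and
   606 Hz / 158 ms for the unsuppressed water reference), including the
   first-order phase from the 1.3 ms acquisition delay.
2. **Synthetic phantom cohort** — a 3D head with smooth GM/WM/CSF
   fractions, ROI labels, log-normal inter-subject concentration
   variability with configurable CV, scalp lipid that bleeds into
   peripheral voxels, macromolecular background and complex Gaussian
   noise; every subject carries known ground truth.
3. **L2-regularised lipid removal** — `x̂ = (I + βLLᴴ)⁻¹ s` with the lipid
   subspace taken from scalp voxels and β chosen by bisection on the
   residual lipid-band amplitude.
4. **Linear-combination fitting** — non-negative amplitudes under global
   shift/damping/phase nuisance parameters over the evaluation ranges
   0.2–1.2 and 1.8–3.88 ppm, with per-compound CRLBs
   (`100·sqrt([F⁻¹]ₘₘ)/Aₘ`, `F = Re(JᴴJ)/σ²`), tCr SNR and linewidth.
5. **Water-referenced quantification** —
   `Cₘ = (Aₘ/A_w)·W_voxel·(E_w,eff/E_m,eff)/(1−f_CSF)` with compartment
   water concentrations 36.1/43.3/53.8 mol/L and 7 T T1 saturation
   correction; no T2 correction (negligible at 1.3 ms delay).
6. **Quality masking** — exclude voxels with tCr SNR < 5, tCr
   FWHM > 0.15 ppm, CRLB > 40% or fit values beyond 13 MADs.
7. **Cohort statistics** — ROI classification (good ≥ 80%,
   acceptable ≥ 66% of voxels with joint NAA/tCr/tCho/mIns CRLB < 40%),
   metabolite qualification, ratios to tCr, and inter-subject CVs
   (`100·SD/mean` of per-subject ROI means).

The per-ROI quality, concentration and CV tables of a published
23-subject 7 T FID-MRSI volunteer cohort ship as labelled transcriptions
(`inst/extdata/reference_roi_*.csv`) so their summary rows can be
recomputed exactly with the package's own statistics code.

## Worked example

```r
library(fidmrsi)

basis       <- build_basis_set(default_resonance_table(), metabolite_acquisition())
water_basis <- build_water_basis()

phantom <- build_phantom(c(16, 16, 8))
phantom <- assign_truth_concentrations(phantom, inter_subject_cv = 10,
                                       n_subjects = 5, seed = 42)
subj <- synthesize_subject(phantom, 1, basis, water_basis, seed = 42)

spec <- subject_spectra(subj)
vox  <- which(phantom$f_wm[subj$voxel_index] > 0.9)[1]   # a deep-WM voxel
fit  <- fit_spectrum(spec$spectra[, vox], basis, noise_sd = subj$noise_sd)
print(fit)
#> Linear-combination fit:
#>             NAA   tCr  tCho   Glu    Gln  mIns   NAAG    MM
#> amplitude 4.435 2.550 0.954 2.798  0.671 2.272  1.084 2.761
#> crlb_pct  3.526 3.862 3.414 4.291 16.362 3.707 12.695 6.495
#>   shift 0.03 Hz, damping 12.05 Hz, phase 0.006 rad, SNR 11.0, FWHM 0.0584 ppm

wfit <- fit_water(subject_spectra(subj, "water")$spectra[, vox],
                  water_basis, noise_sd = subj$noise_sd)
v <- subj$voxel_index[vox]
estimate_concentration(fit$amplitudes["NAA"], wfit$amplitude,
                       c(phantom$f_gm[v], phantom$f_wm[v], phantom$f_csf[v]),
                       "NAA")
#> [1] 11.70   # mM; generator truth at this voxel: 11.80 mM
```

The amplitudes are in generator signal units; CRLB percentages are the
per-compound fit uncertainties (Gln and NAAG are hardest — heavily
overlapped); SNR ≈ 11 and FWHM ≈ 0.058 ppm are the data-quality metrics
the mask thresholds act on. The water-referenced NAA estimate lands within
1% of the known truth at this noise level.

The full study — simulate a cohort, remove lipids, fit, quantify, mask and
aggregate — is one call:

```r
report <- run_pipeline(pipeline_config(n_subjects = 5, seed = 7))
report$cohort$concentration   # per-ROI mean / SD / inter-subject CV
report$roi_classification     # good / acceptable / rejected
write_pipeline_outputs(report, "out/")
```

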