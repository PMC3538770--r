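---
title: "Susceptibility-weighted reconstruction and phase-sign lesion discrimination: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Susceptibility-weighted reconstruction and phase-sign lesion discrimination: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swiprost)
```

## The problem

Susceptibility-weighted imaging (SWI) augments the magnitude of a
gradient-echo MR acquisition with its phase, which carries the sign of local
magnetic-susceptibility deviations: paramagnetic blood products
(deoxyhemoglobin, methemoglobin, hemosiderin) shift the field one way,
diamagnetic calcium deposits the other. In the prostate this matters twice
over — hemorrhage is far more common inside carcinoma than in benign
hyperplastic tissue, and small calcifications that are nearly invisible on
conventional T1/T2-weighted images are conspicuous on the filtered phase
image. Both lesion kinds are *dark* on the SWI magnitude, so the filtered
phase sign is what separates them.

`swiprost` implements the complete computational chain: a
susceptibility-realistic phantom simulator, the SWI reconstruction, a
hypointense-focus detector with a phase-sign classifier, and the
diagnostic-accuracy statistics used at cohort level.

## Forward model (phantom module)

A phantom is a set of non-overlapping spheres, each with a susceptibility
shift $\Delta\chi$ (ppm; positive = paramagnetic = hemorrhage, negative =
diamagnetic = calcification). The induced fractional field shift is computed
with the Lorentz-sphere-corrected k-space dipole kernel

$$\frac{\Delta B}{B_0}(\mathbf r) \;=\;
  \mathcal F^{-1}\!\Big[\Big(\tfrac13 - \tfrac{k_z^2}{|\mathbf k|^2}\Big)\,
  \mathcal F[\chi]\Big],\qquad D(\mathbf 0) := 0 ,$$

with the third grid axis along the main field. Setting $D(\mathbf 0)=0$
makes the volume-mean field shift exactly zero (assertable to $10^{-9}$
ppm). Two consequences of this model are exploited by the tests: the
interior mean field of a uniform sphere vanishes, and uniform slabs see the
classical demagnetisation factors ($-2\chi/3$ normal to the field, $+\chi/3$
transverse), which pin the kernel's scale and axis assignment analytically.

Phase then accrues as
$\varphi = s\,\gamma B_0\,(\Delta B/B_0)\,T_E + \varphi_{\mathrm{bg}}$ with
$\gamma = 2\pi \cdot 42.577$ MHz/T, $s = -1$ for a left-handed phase
convention (the default: paramagnetic sources acquire *negative* local
phase, matching the convention under which hemorrhage reads dark on filtered
phase) and $s=+1$ for right-handed systems. $\varphi_{\mathrm{bg}}$ is a
low-order polynomial standing in for the smooth background static-field
variation; it is exactly what the high-pass filter must remove. Magnitude is
1 in tissue and attenuated by a per-source constant (default 0.5) standing
in for T2\* shortening — a deliberate simplification that makes
calcifications dark on SWI too, as observed clinically, without an
intravoxel-gradient model. Independent Gaussian noise (default sd 0.05) is
added to the real and imaginary channels before magnitude/phase
re-extraction, giving Rician magnitude noise.

Acquisition defaults are a 3 T prostate protocol: $T_E = 12$ ms, 3 mm
slices. The default grid is 96 × 96 × 32 at 1 × 1 × 3 mm — desk-scale
rather than the full in-plane acquisition matrix, chosen so the entire test
suite (including two 96 × 96 × 32 phantom reconstructions and a 20-source
recovery study) runs in well under a minute.

Why does a *uniform sphere*, whose interior field is zero, still show a
phase signature? The external dipole field of a paramagnetic sphere is
negative in the equatorial plane. The 2-D high-pass filter subtracts a local
spatial average from each voxel, and for an interior voxel that average is
contaminated by the surrounding equatorial ring — so the *filtered* interior
phase acquires the sign opposite to the ring, i.e. negative for hemorrhage
under the left-handed convention. This is precisely the mechanism that makes
focal susceptibility sources conspicuous on clinical filtered-phase images,
and the package's end-to-end tests confirm it quantitatively (interior mean
filtered phase ≈ ∓0.34 rad for ±0.5 ppm, 4 mm sources).

## SWI reconstruction

Four deterministic stages, all intermediates returned:

1. **Homodyne high-pass phase filter.** Each slice's complex image
   $m e^{i\varphi}$ is divided by its low-pass version, obtained by
   windowing the central 64 × 64 k-space region; the quotient's phase is the
   filtered phase. Complex division sidesteps phase unwrapping. The window
   (Hann by default, boxcar available) is defined symmetrically about DC on
   integer frequency indices, $w(q)=\tfrac12(1+\cos 2\pi q/L)$ on
   $|q|\le L/2$; symmetry makes the filter exactly odd under complex
   conjugation of the input, so flipping the acquisition handedness negates
   the filtered phase exactly. Slices with identically zero phase are given
   an exactly real low-pass image, so a phase-free input passes through the
   whole reconstruction bit-exactly. Voxels with a zero low-pass magnitude
   (possible only for pathological inputs) get filtered phase 0 and are
   counted in a diagnostic.
2. **Negative-phase mask.** $M(\varphi)=1$ for $\varphi \ge 0$ and
   $M(\varphi)=1+\varphi/\pi$ for $\varphi<0$: positive phase maps to unity,
   negative phase ramps linearly to 0 at $-180^\circ$. $\varphi = 0$ maps to
   1 (both one-sided limits agree).
3. **Mask multiplication.** $\mathrm{SWI} = m \cdot M^4$ — the mask
   "multiplied four times" against the original magnitude, implemented as a
   single multiplication by the fourth power. The exponent is a parameter
   (`mask_exponent`); larger exponents strictly increase contrast wherever
   $M<1$.
4. **Minimum-intensity projection** over non-overlapping slabs of
   `mip_depth` consecutive slices (default 2), trailing partial slab
   projected over what remains. Slab geometry is exposed explicitly
   (`slabs`); displayed section thickness is metadata, since slab depth ×
   slice thickness is the only geometry the data define.

Filtering is per-slice 2-D, matching the 2-D filter specification; the slice
count never enters the filter.

## Lesion detection and classification

Detection operationalises "low signal on SWI": a voxel is hypointense when
its SWI value is below 0.7 × the in-plane local median background (15 × 15
window, constant-time median filter); candidates are 26-connected
components of at least 3 voxels. All these thresholds are engineering
defaults — the clinical reads they stand in for were visual — and are
exposed in `detection_params()`.

Classification applies the phase-sign rule to the *mean* filtered phase over
the focus ("mixed signal dominated by" one sign): with a left-handed
acquisition, mean phase $< -\varepsilon$ ⇒ hemorrhage, $> +\varepsilon$ ⇒
calcification, otherwise indeterminate ($\varepsilon = 0.05$ rad by
default); a right-handed acquisition inverts the rule, so simulating and
classifying under the same convention leaves labels invariant.
Classification depends only on phase, hence is invariant to magnitude
rescaling.

Scoring against ground truth uses greedy one-to-one centroid matching within
5 mm — adequate at phantom source densities and simpler to audit than
optimal assignment. A matched call with the wrong label counts as both a
false positive and a false negative.

On 20-source phantoms (10 paramagnetic, 10 diamagnetic, $|\Delta\chi|$
drawn from 0.2–1 ppm, radii 2–6 mm, noise sd 0.05) the pipeline typically
matches 16–20 of 20 sources and labels 95–100 % of matched lesions
correctly. The occasional failure mode is informative: a small (~2 mm)
source centred between 3 mm slices loses most of its phase signature to
partial voluming and falls inside the indeterminacy margin. The
susceptibility and size ranges are plausible placeholders — the study this
package models reports no quantitative susceptibilities or lesion sizes —
and are not calibrated to literature values.

## Diagnostic statistics

`diagnostic_metrics()` computes sensitivity, specificity, accuracy, PPV and
NPV from a 2 × 2 table against a gold standard, each with an exact
Clopper–Pearson interval; zero-denominator metrics are reported as undefined
(`NA`) with a warning, never coerced. The identity
$\mathrm{acc} = \mathrm{sens}\cdot p + \mathrm{spec}\cdot(1-p)$ (prevalence
$p$) holds exactly and is property-tested.

`fisher_exact()` is a from-scratch two-sided Fisher's exact test: the
conditional hypergeometric point probabilities are computed in log space via
`lchoose`, and the two-sided p-value sums all tables (margins fixed) whose
point probability does not exceed the observed one — the
point-probability/minimum-likelihood convention of mainstream statistical
software, with ties admitted within a relative tolerance of $10^{-7}$. It is
cross-checked in the tests against an independent factorial-enumeration
oracle (to $10^{-9}$) and against `stats::fisher.test` over an exhaustive
sweep of all 2 × 2 tables with total ≤ 14.

Displayed percentages use one-decimal rounding, half away from zero — the
convention that reproduces every printed cohort percentage (82.6, 1.9, 13.6,
75.0, 74.0). An NPV of 54/73 prints as 74.0 under this rule.

`simulate_cohort()` generates two-arm cohorts (prostate cancer vs benign
prostatic hyperplasia) in long format, one row per patient per lesion kind,
with per-modality detection flags. Default prevalences and detection
probabilities are the cohort rates the package models: hemorrhage 19/23
(cancer) vs 1/53 (BPH) with perfect SWI detection and conventional-MRI
sensitivity 7/19; calcification 5/23 vs 17/53 with CT as a perfect gold
standard, SWI 22/22 and conventional MRI 3/22. Since no hemorrhage gold
standard independent of SWI exists in the modelled design, "present" is
identified with SWI-visible at those prevalences.
`build_study_tables()` folds any such cohort back into the hemorrhage ×
disease table and the per-modality calcification-vs-CT tables.

## What the phantom does and does not emulate

Emulated: susceptibility-sign contrast with the correct dipole geometry and
anisotropic voxels, smooth background phase, phase wrapping, T2\*-like
focal signal loss, Rician magnitude noise, vendor handedness. Not emulated:
pulse-sequence/k-space acquisition effects, coil sensitivities, flow and
motion, chemical shift, diffusion narrowing, intravoxel field gradients,
non-spherical lesion shapes, and prostate anatomy (zonal structure is
metadata only). Passing tests therefore demonstrate the correctness of the
reconstruction and of the sign-based discrimination mechanism, not clinical
performance on patient data.

## Numerical choices and degenerate inputs

* Phase is always wrapped to $(-\pi, \pi]$ via
  `pi - ((pi - x) %% (2*pi))`; $3\pi/2 \mapsto -\pi/2$.
* Overlapping phantom sources are rejected (truth labels would be
  ambiguous), naming the offending pair.
* All randomness flows through explicit integer seeds; noiseless synthesis
  is seed-independent and bit-reproducible, and the pipeline manifest
  records an MD5 per artifact so full-run determinism is a hash comparison.
* An all-zero SWI volume yields an empty detection list with a warning;
  empty foci are an error in classification.
* Simulation sizes used in the test suite: 96 × 96 × 32 phantoms for the
  reconstruction and recovery tests, 32³/64³ grids for forward-model
  properties, a 10 000-patient cohort for the binomial convergence check.

## Known limitations

* The k-space forward model is periodic; a single-voxel source's absolute
  far field on a small grid deviates from the free-space point-dipole value
  (the dipole lobe *ratio* is exact). Analytic slab and sphere identities
  are used where absolute validation is needed.
* Sub-slice lesions (≲ slice thickness) can lose their phase signature to
  partial voluming and come out indeterminate.
* The detector's local-median background is 2-D in-plane; strongly sloped
  backgrounds across slices are not compensated.
* DICOM import and vendor phase-scaling quirks are out of scope; NIfTI-1 is
  the single container, with a degrees-to-radians guard on phase input.
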