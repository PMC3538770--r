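# swiprost

Susceptibility-weighted MRI (SWI) reconstruction and phase-sign lesion
discrimination for the prostate, with the cohort-level diagnostic statistics
that go with it.

## The problem

Prostate carcinoma bleeds far more often than benign prostatic hyperplasia
(BPH), and prostatic calcifications are nearly invisible on conventional
T1/T2-weighted MRI. Both hemorrhage and calcification show up as dark foci
on SWI — but they sit on opposite sides of zero in magnetic susceptibility
(blood products paramagnetic, calcium diamagnetic), so the *sign* of the
high-pass-filtered phase separates them. This package implements the full
computational chain for studying that mechanism:

* **phantom** — synthesis of realistic gradient-echo magnitude/phase volumes
  from declarative susceptibility phantoms: k-space dipole forward model
  `D(k) = 1/3 − k_z²/|k|²` (Lorentz-corrected, `D(0) = 0`), polynomial
  background phase, T2\*-like focal attenuation, complex Gaussian noise;
  plus a two-arm patient-cohort simulator;
* **reconstruction** — slice-wise homodyne high-pass phase filtering
  (central 64 × 64 k-space window, Hann or boxcar), the negative-phase mask
  (`M = 1` for φ ≥ 0, ramping linearly to 0 at −180°), fourth-power mask
  multiplication `SWI = m·M⁴`, and minimum-intensity projection over
  two-slice slabs;
* **lesion calling** — hypointense-focus detection (local-median background,
  3-D connected components) and hemorrhage/calcification classification by
  the sign of the focus-mean filtered phase, scored against phantom ground
  truth;
* **diagnostics** — sensitivity/specificity/accuracy/PPV/NPV with exact
  Clopper–Pearson intervals, exact binomial detection rates, and a
  from-scratch two-sided Fisher's exact test (log-space hypergeometric,
  point-probability convention).

## Worked example

A 96 × 96 × 32 phantom (1 × 1 × 3 mm voxels, 3 T, TE 12 ms) with one
hemorrhage (+0.5 ppm) and one calcification (−0.5 ppm), both 4 mm, noise
sd 0.05:

```r
library(swiprost)

spec <- phantom_spec(
  sources = list(
    susceptibility_source(c(30, 48, 16), radius = 4, delta_chi = +0.5,
                          kind = "hemorrhage"),
    susceptibility_source(c(66, 48, 16), radius = 4, delta_chi = -0.5,
                          kind = "calcification")),
  noise_sd = 0.05, seed = 7)

sim   <- simulate_phantom(spec)
rec   <- reconstruct_swi(sim$volume, recon_params())
calls <- classify_lesions(rec, detection_params(), handedness = spec$handedness)
as.data.frame(calls)
#>   id cx   cy cz n_voxels mean_phase_rad swi_contrast         label
#> 1  1  1  5.4  7        5         -0.304        0.321    hemorrhage
#> 2  2 30 48.0 16       94         -0.338        0.645    hemorrhage
#> 3  3 66 48.1 16      109          0.199        0.485 calcification
```

Both sources are found at their true centres and labelled correctly: the
paramagnetic source carries negative mean filtered phase (−0.34 rad,
left-handed convention) and the diamagnetic one positive (+0.20 rad). Call 1
is a small noise/edge artifact at the volume boundary — scoring against the
ground truth counts it as the one false positive:

```r
evaluate_against_truth(calls, sim$truth, spec$voxel_size)$counts
#>            kind tp fp fn
#> 1    hemorrhage  1  1  0
#> 2 calcification  1  0  0
```

Cohort statistics work directly from printed 2 × 2 counts. Conventional
MRI's calcification detection against the CT gold standard (3 of 22 CT-
positive patients detected, no false positives among 54 CT-negative):

```r
diagnostic_metrics(contingency_2x2(tp = 3, fn = 19, fp = 0, tn = 54))
#> sensitivity   13.6% (3/22; 95% CI 2.9-34.9%)
#> specificity  100.0% (54/54; 95% CI 93.4-100.0%)
#> accuracy      75.0% (57/76; 95% CI 63.7-84.2%)
#> ppv          100.0% (3/3; 95% CI 29.2-100.0%)
#> npv           74.0% (54/73; 95% CI 62.4-83.5%)

fisher_exact(matrix(c(19, 4, 1, 52), 2, byrow = TRUE))
#> Fisher's exact test (two-sided, hypergeometric point-probability): p = 4.32184e-13
```

The hemorrhage-by-disease association (19/23 cancer vs 1/53 BPH) is
overwhelmingly significant.

`run_pipeline(config, out_dir)` chains
simulate → reconstruct → detect → evaluate → stats from a YAML/JSON or
in-memory config, writing NIfTI volumes, TSV tables and a manifest with an
MD5 per artifact (same config + seed ⇒ identical hashes). A thin CLI over
the same functions lives at `inst/cli/swiprost.R`
(`pipeline` / `reconstruct` / `stats` subcommands).

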