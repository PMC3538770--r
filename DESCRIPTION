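Package: swiprost
Title: Susceptibility-Weighted MRI Reconstruction and Phase-Sign Lesion
    Classification for the Prostate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates susceptibility-realistic gradient-echo magnitude and
    phase volumes from declarative phantom specifications (k-space dipole
    forward model, polynomial background phase, complex Gaussian noise),
    reconstructs susceptibility-weighted images (SWI) by homodyne high-pass
    phase filtering, negative-phase masking, fourth-power mask multiplication
    and minimum-intensity projection, detects hypointense foci and classifies
    them as hemorrhage or calcification from the sign of the filtered phase,
    and computes diagnostic-accuracy statistics (sensitivity, specificity,
    accuracy, PPV, NPV, exact binomial detection rates, and a from-scratch
    two-sided Fisher's exact test) for cohort-level evaluation against a
    gold-standard modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
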