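Package: ecmonirs
Title: Severity Classification of ECMO Patients from Lower-Limb NIRS Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing lower-limb near-infrared spectroscopy (NIRS)
    recordings acquired during a staged ECMO pump-speed protocol. The package
    simulates protocol-locked hemodynamic signals for synthetic cohorts,
    converts optical densities to hemoglobin concentration changes via the
    modified Beer-Lambert law, applies zero-phase Butterworth low-pass
    filtering and min-max normalization, extracts stage-based feature families
    (stage mean, activation, difference, slope), screens features with
    independent-samples t-tests, and classifies high- versus low-severity
    (APACHE II) patients with an RBF-kernel support vector machine, optionally
    fusing NIRS features with clinical covariates through principal component
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
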