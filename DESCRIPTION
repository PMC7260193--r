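Package: fusbbb
Title: Closed-Loop Cavitation Control and Quantification for Focused
    Ultrasound Blood-Brain Barrier Opening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse microbubble-mediated blood-brain
    barrier (BBB) disruption with a low-frequency transcranial focused
    ultrasound system.  Implements per-burst spectral feature extraction
    (harmonic, subharmonic and broadband emission levels relative to noise
    floors), a proportional closed-loop acoustic power controller with
    safety triggers, volumetric sonication planning (36-target grids, ROI
    masks, focal energy-density maps), variable-TR R1 relaxometry with
    gadolinium concentration estimation, spin-echo enhancement prediction,
    and geometric-mean pharmacokinetic statistics with LLOQ censoring.
    Seeded synthetic-data generators for burst spectra, saturation-recovery
    MRI phantoms and paired drug-concentration samples make the whole
    pipeline testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    knitr
Config/testthat/edition: 3
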