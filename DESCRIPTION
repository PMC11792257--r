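Package: ck2coh
Title: Causal Squared Coherence for Cardiovascular and Cardiorespiratory Beat Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based spectral directional analysis of the closed-loop
    interactions between heart period (HP), systolic arterial pressure (SAP)
    and respiration (RESP). Extracts beat-to-beat variability series from raw
    ECG/arterial-pressure/respiration recordings, computes univariate
    autoregressive spectral markers (LF/HF band powers, respiratory frequency)
    via Levinson-Durbin identification and residue-theorem spectral
    decomposition, fits bivariate autoregressive models with direction-specific
    latencies to obtain squared coherence (K2) and causal squared coherence
    (CK2) averaged in the LF and HF bands, and tests markers against an
    uncoupling null built from iteratively refined amplitude-adjusted Fourier
    transform (IAAFT) surrogate pairs. Includes seed-deterministic synthetic
    closed-loop generators with known directional coupling for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
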