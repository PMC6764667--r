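Package: pulsevar
Title: Respiratory Variation in Pulse Pressure, Photoplethysmogram and
    Central Venous Pressure from Multichannel Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the dynamic preload variables dPP (respiratory
    variation in arterial pulse pressure), dPOP (respiratory variation in
    photoplethysmographic waveform amplitude) and dCVP (peak-to-trough
    respiratory swing in central venous pressure) from synchronized
    multichannel physiological recordings, and models how they track
    progressive central hypovolemia under graded expiratory resistance
    (PEP) or continuous positive airway pressure (CPAP). Includes ECG
    R-peak detection, wavelet-ridge respiratory cycle segmentation,
    Doppler velocity-time-integral stroke volume, per-cycle quality
    control, a linear mixed-effects slope model with single-step
    multiplicity-adjusted contrasts, and a synthetic waveform generator
    with known ground truth so the whole pipeline can be validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    multcomp,
    optparse
Config/testthat/edition: 3
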