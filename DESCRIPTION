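Package: rppgmodel
Title: Forward Modelling and Calibration of Reflective Arterial Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative model of the reflective photoplethysmography (rPPG)
    signal over a peripheral artery. Composes a constant background irradiance,
    a blood-volume (pressure) pathway linearised through the arterial
    pressure-diameter law, and a blood-flow pathway driven by shear-dependent
    red-blood-cell orientation with biexponential disorientation/aggregation
    kinetics after flow deceleration. Includes a synthetic waveform generator
    emulating static pressure steps, flow sweeps, pulsatile and
    intermittent-flow mock-circulatory protocols; calibration of every model
    constant by linear and nonlinear least squares; and agreement and spectral
    evaluation machinery (Pearson correlation, Bland-Altman limits, Welch
    magnitude-squared coherence, Morlet wavelet coherence with phase, per-beat
    counter-phase detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
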