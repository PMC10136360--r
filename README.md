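# rppgmodel

Forward modelling and calibration of the **reflective arterial
photoplethysmography (rPPG)** signal.

The rPPG waveform recorded over a peripheral artery such as the radial is
often treated as a surrogate for blood volume — and hence for intraluminal
pressure. This package implements a quantitative model in which the signal is
instead driven by *two* comparable mechanisms, and provides the machinery to
calibrate, simulate and evaluate it:

* a **volume pathway**: light attenuation grows with the lumen diameter,
  which is linear in pressure over 50–200 mmHg
  (`D = D_ref + b (P − P_ref)`), so this pathway is linear in pressure,
  `E_V ≈ a′ + b′P`, with a *positive* PPG contribution;
* a **flow pathway**: shear aligns the disk-shaped red blood cells with the
  flow, raising backscatter along a saturating law,
  `E_Q = m′ (Q/Q_c)/(1 + Q/Q_c)`, with a *negative* PPG contribution under
  the standard sign convention. When flow decelerates, alignment and
  disaggregation relax biexponentially,
  `(r e^{−t/τ_d} + e^{−t/τ_a})/(r + 1)` with `r = n_d/n_a`, the
  disorientation-to-aggregation amplitude ratio.

The predicted signal is `PPG = a′ + b′P − E_Q(Q)` (a.u.). Because the two
pathways are of comparable magnitude, pressure-only predictions fail in both
the time and frequency domains, and beats whose flow effect dominates appear
in **counter-phase** with pressure — reproduced here below 100 mmHg systolic
and absent at high pressure.

A synthetic waveform generator emulates the four mock-circulation protocols
(static pressure steps, flow sweeps at constant pressure, pulsatile flow
against resistance, intermittent flow with 10-s pauses), so the whole
pipeline runs without any experimental data. The bundled calibrated
constants are: slope 2.15 a.u./mmHg, `m′` = 1613 a.u., `Q_c` = 328 mL/min
(critical shear rate 870 s⁻¹ via the Poiseuille conversion
`γ̇ = 32Q/(πD³)`), `τ_d` = 0.39 s, `τ_a` = 1.78 s, `n_d/n_a` = 2.2 (3.6 for
aggregation-inhibited blood), receiver exponent `d` = 1.3, wall slope
`b` = 1.245×10⁻³ mm/mmHg.

## Worked example

Generate a stiff-vessel flow sweep with forward-modelled PPG and recover the
saturation constants; then estimate the decay kinetics from an
intermittent-flow run:

```r
library(rppgmodel)
k <- reference_constants()

spec <- protocol_spec("flow_sweep", seed = 42,
                      flow_levels = seq(0, 800, length.out = 12),
                      level_duration = 5)
rec <- simulate_recording(spec, vessel_model(is_stiff = TRUE), k,
                          with_ppg = TRUE)
rec
#> <hemodynamic_recording> flow_sweep: 71000 samples @ 1000 Hz (71.0 s), with PPG
#>   pressure 98.0-102.2 mmHg, flow -7.5-807.2 mL/min
fit_flow_saturation(rec)
#> <ppg_fit>
#>   m_prime      1612.68  (SE/SD 0.178)
#>   Q_c          327.896  (SE/SD 0.114)
#>   K            214.94  (SE/SD 0.0784)
#>   R^2 = 1.0000, n = 12

spec2 <- protocol_spec("intermittent", seed = 7, n_pulses = 5)
rec2 <- simulate_recording(spec2, k$vessel, k, with_ppg = TRUE)
fit_biexponential(rec2)
#> <ppg_fit>
#>   tau_d        0.390732  (SE/SD 0.000731)
#>   tau_a        1.78298  (SE/SD 0.00731)
#>   nd_na_ratio  2.20761  (SE/SD 0.0159)
#>   R^2 = NA, n = 5
```

The saturation fit recovers `m′` and `Q_c` from the noisy sweep (the
half-saturation flow, 328 mL/min, is where `E_Q` reaches `m′/2` = 806.5
a.u.); the per-pause decay fits recover both time constants and the
amplitude ratio, pooled as mean (SD) over the pauses.

Other entry points: `predict_ppg()` (modes `"P_and_Q"` / `"P_only"`),
`agreement()` (Pearson + Bland–Altman), `welch_msc()` (2048-point
rectangular windows, 1024 overlap), `wavelet_coherence()` (Morlet, phase +
cone of influence), `beat_phase()` (counter-phase flags),
`calibrate_recording()` (protocol-dispatched fits), `read_config()` /
`simulate_recording()` (JSON/YAML configs, CSV output with provenance
sidecar).

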