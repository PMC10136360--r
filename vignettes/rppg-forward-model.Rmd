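---
title: "Modelling the reflective arterial PPG signal from pressure and flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the reflective arterial PPG signal from pressure and flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rppgmodel)
```

## The model

Reflective photoplethysmography (rPPG) over a peripheral artery measures the
irradiance returned to a probe from an illuminated vessel and its
surroundings. The package decomposes that irradiance into three terms,

\[ E = E_{DC} + E_V + E_Q, \]

a constant background from the surrounding tissue (here, a fixed reflector),
a **volume pathway** \(E_V\) governed by intraluminal pressure, and a **flow
pathway** \(E_Q\) governed by red-blood-cell (RBC) orientation. The receiver
maps irradiance to the recorded voltage through a power law
\(V = c\,E^{d}\) with \(d = 1.3\) for the phototransistor modelled here;
because the pulsatile fluctuations are small relative to the operating point,
all calibrated constants are expressed directly in post-receiver arbitrary
units (a.u.), and `sensor_response()` is provided separately for
irradiance-domain work.

**Volume pathway.** Light transmission through blood under a diffusion
approximation gives \(E_V = E_0 e^{-\mu_a z}\cosh\!\big(z\sqrt{2\mu_a
\mu_s'}\big)\) with the optical path \(z\) tied to the lumen diameter
(`ev_diffusion()`; the cosh argument is read as \(z\sqrt{2\mu_a\mu_s'}\),
the only dimensionally consistent grouping of the stated constants). Over
the 50–200 mmHg range the arterial pressure–diameter relation is close to
linear (`vessel_model()`, slope \(b\) in mm/mmHg), so the pathway linearises
to \(E_V \approx a' + b' P\) (`ev_from_pressure()`); the package works with
the linear form throughout and keeps the diffusion form as a documented
alternative whose tangent at the reference pressure reproduces \(a', b'\)
(`linearize_diffusion()`).

**Flow pathway.** Disk-shaped RBCs align with the flow under shear and
scatter light preferentially toward the lateral (probe) direction. The
aligned fraction follows a saturating law of shear rate,
\(p^* = m\,\dot\gamma/\dot\gamma_c / (1 + \dot\gamma/\dot\gamma_c)\)
(`aligned_fraction()`), which in the flow domain becomes

\[ E_{Q,H} = m' \frac{Q/Q_c}{1 + Q/Q_c} \]

(`eq_high()`), half-saturating at the critical flow rate \(Q_c\). The two
domains are linked by the Poiseuille wall shear rate
\(\dot\gamma = 32 Q / (\pi D^3)\) (`wall_shear_rate()`).

When flow decelerates, alignment is lost with time constant \(\tau_d\)
(disorientation) and rouleaux form with time constant \(\tau_a\)
(aggregation), both of which raise reflectance transiently; orientation and
disaggregation on acceleration are fast enough to be treated as
instantaneous. After an abrupt stop from flow \(Q_0\) the flow-pathway
irradiance relaxes as

\[ E_Q(t) = E_{Q,H}(Q_0)\,
   \frac{r\,e^{-t/\tau_d} + e^{-t/\tau_a}}{r + 1}, \qquad r = n_d/n_a, \]

the shape of the normalised biexponential kernel (`decay_kernel()`), in
which only the amplitude ratio \(r\) is identifiable.

Under the usual sign convention (a pressure rise increases PPG, i.e.
reduces reflected light) the flow term enters the PPG with negative sign:

\[ \mathrm{PPG}(t) = a' + b' P(t) - E_Q(t). \]

`predict_ppg()` evaluates this in `"P_and_Q"` mode, or with the flow term
zeroed in `"P_only"` mode (the volume-only hypothesis). With the bundled
constants the two pathways have comparable magnitude over physiological
ranges, which is why pressure-only predictions fail in the frequency domain
and why **counter-phase beats** — PPG roughly 180° out of phase with
pressure — emerge wherever the flow contribution outweighs the pressure
contribution (low systolic pressure with a strong flow pulse).

## Flow-pathway dynamics: a state model, not a linear convolution

A naive causal convolution of the instantaneous drive \(E_{Q,H}(Q(t))\) with
the unit-integral kernel cannot reproduce the relaxation above: for a
step-to-zero input a linear filter's output decays as the kernel's *tail
integral*, whose component weights are \(r\tau_d : \tau_a\) rather than
\(r : 1\). The kinetics the decay fits measure are those of the kernel shape
itself, so the package implements the pathway as a two-component state model
(`eq_flow_series()`):

* the orientation component (weight \(r/(r+1)\)) and the aggregation
  component (weight \(1/(r+1)\)) each track the saturating drive
  instantaneously while the drive exceeds their decayed state;
* when the drive falls, each component relaxes exponentially with its own
  time constant.

This reduces exactly to \(E_{Q,H}(Q)\) for steady or accelerating flow,
produces exactly the kernel-shaped biexponential during pauses, is
continuous at regime boundaries by construction, and keeps the memory of a
strong earlier pulse alive through the slow aggregation component even if a
weaker pulse intervenes. The fast implementation is an \(O(n)\) recursion;
the test suite checks it to \(10^{-9}\) relative against an \(O(n^2)\)
direct-search evaluation of the same definition and to \(10^{-6}\) against
the closed-form step response. `classify_regimes()` labels samples
high/low-shear (smoothed 50-ms derivative, flow threshold
`decel_flow_fraction * Q_c` = 0.5 by default, 20-ms hysteresis) for
inspection and reporting; the state model itself needs no labels.

## The synthetic generator

No raw recordings are deposited, so every downstream stage is exercised on
synthetic recordings that emulate the four mock-circulation protocols
(1 kHz sampling throughout):

* **static steps** — pressure plateaus joined by 1-s raised-cosine ramps,
  zero flow;
* **flow sweep** — flow plateaus (held ≥ 4 s, matching the 4-s averaging
  convention of the saturation fit) at constant pressure, preferably with a
  stiff segment so the diameter cannot respond;
* **pulsatile** — periodic beats: a truncated-Fourier pressure template
  (fundamental plus three harmonics with fixed phases, rotated to start at
  the diastolic minimum and min–max scaled to the requested range) and a
  gamma-shaped systolic flow ejection (peak at 25 % of the beat, shape
  parameter 4). Both are smooth and band-limited far below the 50-Hz
  analysis filter;
* **intermittent** — isolated flow pulses (0.3-s rise, 2-s hold) ending in
  an instantaneous stop, separated by 10-s zero-flow pauses. The abrupt stop
  mirrors a pump halt and makes the pause decay exactly biexponential from
  its first sample, which is what lets noiseless decay fits recover the
  generating constants to machine precision.

Noise is additive, independent and Gaussian per channel with defaults
0.5 mmHg (pressure), 2 mL/min (flow), 5 a.u. (PPG) and 0.008 mm (diameter);
the diameter value is sized once so that the wall-law fit on a 50–200 mmHg
ramp lands near the coefficient of determination reported for the physical
artery model (R² ≈ 0.98). The forward-modelled PPG responds to the
*noiseless* pressure and flow (the physical signal responds to the true
hemodynamics; measurement noise lives on the recorded channels), and each
generated recording retains those noiseless channels in its `truth` field.
All draws descend from one explicit seed per call — identical spec, vessel
and seed give bit-identical recordings — and the master seed of
`reproduce_study()` spawns per-stage child seeds deterministically.

What the generator does **not** emulate: wave propagation or Windkessel
dynamics (waveforms are phenomenological templates), wall viscoelasticity
(the hysteresis time constant of the physical model, 0.06–0.08 s, is small
against \(\tau_d\) and \(\tau_a\)), drift, motion artifacts, or beat-to-beat
variability. Passing tests therefore demonstrate the internal consistency of
the model and estimators under the stated noise model, not robustness to
real-world artifacts.

## Calibration

* `fit_pressure_slope()` — OLS of plateau-averaged PPG on plateau pressure.
  Plateaus are found by a variance change-point rule on 1-s windows (a
  window is plateau-like when its SD stays at the noise floor; runs shorter
  than 4 s are discarded; 0.5-s margins are trimmed), matching the 4-s
  averaging convention.
* `fit_flow_saturation()` — nonlinear least squares of plateau means against
  the saturating law, five multi-start \(Q_c\) guesses log-spaced over the
  observed flow range (saturating fits are sensitive to initialisation),
  Gauss–Newton standard errors from the Jacobian; a fit whose \(Q_c\)
  standard error explodes (straight-line data, no curvature) is flagged
  `converged = FALSE`.
* `fit_biexponential()` — per-pause fits of
  \(C + A\,(r e^{-t/\tau_d} + e^{-t/\tau_a})\) with \(t = 0\) at the end of
  deceleration (one sample before the first pause sample), the ordering
  \(\tau_d < \tau_a\) enforced by parameterisation
  (\(\tau_a = \tau_d(1+e^{\varphi})\), \(\log r\), \(\log\tau_d\)), five
  start pairs, and pooling across pauses into mean (SD), the convention used
  for protocol-level reporting. The Jacobian condition number is recorded
  per pause (warning above \(10^6\)), as biexponentials with nearby time
  constants are notoriously ill-conditioned.
* `fit_pressure_diameter()` — OLS of diameter on pressure (slope \(b\)).

## Evaluation

`lowpass_50()` is a zero-phase 50-Hz low-pass. A 4th-order Butterworth at
50 Hz would lose ~1.3 dB at 40 Hz after forward–backward application, which
is incompatible with keeping the 0–40-Hz band untouched, so the filter is a
linear-phase FIR (Hamming windowed-sinc, 201 taps at 1 kHz, taps normalised
to exact unit DC gain) applied with reflection padding and group-delay
compensation: passband ripple below 40 Hz is under 0.1 dB and a 100-Hz tone
is attenuated by over 97 %.

`agreement()` reports Pearson's r on instantaneous values and Bland–Altman
bias (mean, SD, mean ± 1.96 SD limits) on predicted-minus-measured
differences. `welch_msc()` estimates magnitude-squared coherence by
overlapped averaged periodograms with 2048-sample rectangular windows and
1024-sample overlap (window duration preserved in seconds at other sampling
rates); series are demeaned once so the estimate is invariant to scaling and
offsets. `wavelet_coherence()` is the standard Morlet (\(\omega_0 = 6\))
construction: scale-normalised cross-spectrum, Gaussian time smoothing of
width equal to the scale, boxcar scale smoothing over 0.6 octave, phase
convention 0 = in phase / \(\pi\) = counter-phase, and a cone of influence
from the \(\sqrt{2}s\) e-folding time; phase is conventionally displayed
only where coherence exceeds 0.5 (`high_coherence`). `beat_phase()` takes
the cross-spectrum phase at each beat's fundamental bin and flags a beat
counter-phase when \(|\phi| > \pi/2\) — the midpoint separating "in phase or
small delay" from "counter-phase or large delay"; the final beat is given a
window of the median beat length so its fundamental bin stays on the beat
frequency.

## Reproduction scenarios and problem sizes

`reproduce_study()` regenerates every calibrated constant from synthetic
protocols at the stated noise levels: 100 Monte-Carlo seeds for the static
slope (10 plateaus, 50–200 mmHg, 6 s each), the flow saturation (12
plateaus, 0–800 mL/min, 5 s each, stiff vessel; medians reported, as the
per-seed sampling distribution of saturating fits is mildly skewed) and the
wall slope (20-s ramps); one 20-pause intermittent batch per blood
condition for the decay kinetics (pooled means); plus the
inhibitor-contrast arithmetic, a Welch two-sample test between the
per-pause amplitude ratios of the two blood conditions, the counter-phase
demonstration and the pressure-only versus pressure-plus-flow comparison
(12 pulsatile beats, 80–120 mmHg, 0–600 mL/min).

The counter-phase demonstration uses a flow pulse of 300–420 mL/min with
pressure beats of 75–92 mmHg (low) and 100–160 mmHg (high). These follow
from the calibrated magnitudes: the flow pulse moves \(E_Q\) by roughly
90 a.u., sitting between the pressure-term excursions of the two cases
(≈ 37 and ≈ 129 a.u.), so the flow term dominates the beat fundamental only
in the low-pressure case.

```{r demo}
k <- reference_constants()
spec <- protocol_spec("pulsatile", seed = 1, pressure_range = c(75, 92),
                      flow_range = c(300, 420), heart_rate = 60, n_beats = 4,
                      noise_sd = list(pressure = 0, flow = 0,
                                      diameter = 0, ppg = 0))
rec <- generate_pulsatile(spec, k$vessel)
ppg <- predict_ppg(rec, k$pressure, k$flow)
beat_phase(ppg, rec$pressure, rec$beat_onsets, rec$sampling_rate)
```

## Numerical choices and degenerate inputs

* Kernel truncation at `kernel_horizon = 8 * max(tau_d, tau_a)` (truncation
  error below \(e^{-8}\)); the sampled kernel is renormalised after
  truncation.
* An optional first-order orientation lag (\(\tau_o \approx 0.05\) s) is a
  documented possibility but off by default: orientation is treated as
  instantaneous.
* Degenerate calibration inputs fail loudly: constant pressure (singular
  design), fewer than three plateaus, nonzero flow in a static fit, missing
  PPG channel, straight-line saturation data (flagged, not silently fitted).
* Pauses shorter than \(5\tau_a\) trigger an incomplete-decay warning.
* `welch_msc()` names its minimum record length in its error; `lowpass_50()`
  refuses signals shorter than three filter lengths.

## Known limitations

* The model is single-wavelength; oxygenation effects are outside scope.
* \(E_V\) and \(E_Q\) are treated as additive, which is justified only while
  both are small fractions of the incident irradiance.
* The artery-segment reference diameter (4.0 mm) is inferred by inverting
  the Poiseuille relation at the calibrated \(Q_c\) and \(\dot\gamma_c\),
  not measured.
* Headline agreement statistics on real recordings (correlation, bias,
  band-mean coherence of pressure-only versus pressure-plus-flow
  predictions) depend on the specific in-vitro recordings and are therefore
  validated *directionally* on synthetic data — the pressure-plus-flow
  prediction must dominate in r, bias magnitude and 0–10-Hz coherence — not
  numerically.
* The inverse problem (estimating pressure from a measured PPG) is a
  non-goal of this package.
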