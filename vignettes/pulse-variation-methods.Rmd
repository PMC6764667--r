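---
title: "Methods: dynamic preload variables under graded airway pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic preload variables under graded airway pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the measurement
model, the statistical model, the synthetic-data generator that provides
ground truth, the numerical choices, and the limits of what passing tests
demonstrate.

## The physiological problem

Cyclic intrathoracic pressure changes during breathing modulate venous
return; when the heart operates on the steep part of the Frank–Starling
curve, this modulation is visible as beat-to-beat variation in stroke
volume, hence in pulse pressure (dPP) and in the amplitude of the
photoplethysmographic pulse (dPOP). These *dynamic variables* index
preload dependence. During spontaneous breathing the swings are usually
too small to be informative; an expiratory resistor (PEP) or continuous
positive airway pressure (CPAP) amplifies them. The analysis this package
implements asks: how steeply do dPP, dPOP and the respiratory swing in
central venous pressure (dCVP) rise per step of progressive central
hypovolemia (modelled by lower body negative pressure, LBNP, at 0/20/40/
60/80 mmHg), and does the level of airway pressure (0/5/10 cmH₂O) change
that steepness?

## Measurement model

Per cardiac beat, gated by ECG R peaks (beat window = R-to-R, half-open):

* pulse pressure `PP = max − min` of arterial pressure in the window
  (diastolic is taken as the window minimum rather than the pre-upstroke
  minimum: identical on clean morphology, simpler, and documented as a
  difference on noisy data);
* PPG amplitude `POP = max − min` of the PPG in the window, invariant to
  oximeter gain and offset;
* Doppler `VTI` = trapezoidal integral of the aortic velocity envelope
  over the contiguous region around the beat's velocity peak where
  velocity ≥ 10 % of the peak (0 if the peak is below a 5 cm/s noise
  floor); stroke volume `SV = VTI / cos(20°) · π (2 cm / 2)²` with the
  conventional assumed geometry (beam angle 20°, aortic diameter 20 mm);
  the division by `cos(angle)` is the physics of Doppler projection — the
  beam sees only the velocity component along itself.

Per respiratory cycle, with at least 3 valid member beats (the maximum
and minimum must come from distinct beats; at ~5 beats per cycle this is
the practical floor):

```
dPP  = (PPmax − PPmin)  / ((PPmax + PPmin) / 2)  × 100 %
dPOP = (POPmax − POPmin) / ((POPmax + POPmin) / 2) × 100 %
dCVP = peak − trough of the CVP waveform, after downsampling to 40 Hz
```

The 40 Hz downsampling precedes the peak/trough search (that order is
part of the definition); the anti-alias filter is zero-phase so CVP
extremes are not displaced in time.

### Respiratory segmentation

No airflow is recorded in this protocol, so cycles are found on a
surrogate: low-pass-filtered CVP when present (its respiratory swings
dominate under airway-pressure loading), else the PPG baseline, else a
cubic interpolation of the per-beat pulse-pressure series; the chosen
source is recorded on the returned signal. The surrogate is analyzed with
an analytic Morlet continuous wavelet transform (ω₀ = 6) over 0.08–0.6 Hz
(4.8–36 breaths/min); the ridge of maximum time-averaged power gives the
dominant respiratory frequency `f_r`; the signal is band-passed around
`[0.5 f_r, 2 f_r]` and cycle boundaries are successive troughs (local
minima at least `1/(1.5 f_r)` apart). Cycles run trough-to-trough;
partial cycles at segment edges are discarded. If less than 40 % of the
band power concentrates within ±25 % of the ridge, a no-respiration error
is raised — white noise spreads its power across the band and fails this
test, a flat signal fails earlier on variance.

### Quality control

The published workflow inspected every cycle visually; this package
replaces that with explicit, configurable rules (`qc_thresholds()`), each
rejection logged with a reason: cycle duration outside [1.5, 12] s, fewer
than 3 valid beats, any non-positive member pulse pressure, dPP or dPOP
above 150 %, or an adjacent-beat PP jump larger than 50 % of the sequence
median. Sequence summaries use a 5 % trimmed mean for the static
hemodynamics (SV, HR from R-R intervals, MAP, mean CVP) — trimming
`k = floor(0.05 n)` per tail, so nothing is trimmed below n = 20; the
floor rule is stated because rounding conventions differ — and the median
over accepted cycles for the dynamic variables. The model is fit on
cycle-level observations by default (the sequence medians are also
exposed); cycle level matches an analysis of "all observations in all
subjects" and gives the residual its natural within-sequence spread.

## Statistical model

Per intervention (PEP and CPAP analyzed separately) and outcome:

```
g(y) = β₀ + β_r + (β_slope + γ_r) · step + b_subject + ε
```

with `step = LBNP / 20` continuous, resistance a factor with reference
0 cmH₂O, a random intercept per subject, and Gaussian REML estimation
(lme4). `g = log_e` for dPP and dPOP — they are right-skewed on the
original scale, and a log-linear rise per step matches the curved
original-scale trajectories — and the identity for dCVP, whose effect
sizes are naturally in mmHg per step. Design choices, each resolvable
against the fitted object:

* **LBNP coded as step index (level/20)**, not raw mmHg: slope magnitudes
  of ~0.1 per step (log scale) and ~1 mmHg per step (dCVP) are the
  physiologically interpretable scale.
* **Random intercept only**: the clustering to account for is
  within-subject correlation; a random slope is not identifiable with ~5
  sequences per subject-condition and is not part of the target analysis.
* **Wald normal reference** for CIs and p-values: the cycle-level n is in
  the hundreds; symmetric Wald intervals are what the target tables'
  arithmetic implies.
* **Gaussian REML rather than penalized quasi-likelihood**: for a
  Gaussian response with identity link the two estimands coincide; REML
  is the standard, better-tested path.

Per-level slopes are `β_slope + γ_r` with standard errors from the
corresponding contrast of the coefficient covariance. Pairwise slope
differences (5−0, 10−0, 10−5) are tested with the single-step max-|z|
adjustment: adjusted `p_i = P(max_j |Z_j| ≥ |z_i|)` under a zero-mean
multivariate normal with the contrasts' correlation matrix, evaluated by
seeded Monte Carlo with 10⁵ draws (reproducible to ~3 decimals; the
covariance is repaired by eigenvalue clipping if numerically indefinite,
and adjusted p-values are clamped to the `[p_raw, m · p_raw]` envelope).
`mvtnorm`/`multcomp` reproduce these numbers and serve as independent
cross-checks in the test suite, not as the implementation.

## The synthetic-data generator

`simulate_truth()` draws the sequence-level ground truth from exactly the
mixed model above — subject intercepts `N(0, 0.3²)`, sequence residuals
`N(0, 0.25²)` on the log scale — then `simulate_study()` renders
waveforms carrying those targets. Defaults are chosen once to match the
magnitudes reported for this protocol: baseline dPP 8 % and dPOP 10 % at
LBNP 0, reference slopes 0.09 (dPP) and 0.06 (dPOP) per step on the log
scale, interaction modifiers (0, 0.05, 0.08) for 0/5/10 cmH₂O, dCVP
3 mmHg baseline rising 0.5 mmHg per step with PEP-level-dependent extra
slope (0, 0.5, 0.6 mmHg/step), respiratory rate N(14, 2) breaths/min,
heart rate N(70, 5) + 3 per step, stroke volume 75 ml declining 12 % per
step, MAP 90 mmHg, mean PP 45 mmHg, mean CVP 6 mmHg. CVP is rendered for
at most 10 subjects, mirroring partial catheterization. The optional
dropout argument truncates higher LBNP steps per subject to reproduce a
completion pattern such as 20/19/13/5 without modelling tolerance
physiology. Every sequence lasts `breaths_per_sequence` (default 6)
complete respiratory cycles plus padding.

Waveform construction:

* **Beats**: R-peak times at the nominal R-R interval with Gaussian
  timing jitter (10 ms), aligned to the 10 ms grid shared by the 300 and
  400 Hz channel rates so that each beat's diastolic foot and systolic
  peak fall exactly on samples — the known-truth contract is then free of
  subsample aliasing.
* **Morphology**: linear systolic upstroke over 0.12 s, exponential decay
  (τ = 0.35 s) back toward the diastolic level — the simplest shape with
  unambiguous per-beat max/min. Respiratory modulation is applied to the
  beat-level amplitude sequence, sampled at the R times
  (`PP_i = PP̄ (1 + (dPP/200) sin 2π f_r t_i)`), matching how pulse
  pressure variation is physiologically expressed beat to beat; the
  normalization by the mid-range makes the (max−min)/mean statistic
  recover the target exactly in the dense-beat limit.
* **PPG**: same construction in arbitrary units plus an additive
  respiratory baseline wander (default 0.05 a.u. against a mean beat
  amplitude of 1), which perturbs per-beat max−min only through its
  within-window drift — an error budget of well under one percentage
  point — and exercises the extraction's robustness.
* **CVP**: respiratory sinusoid of the target peak-to-trough amplitude
  plus a 0.5 mmHg cardiac bump per beat. PEP-like rendering raises only
  the expiratory (positive) half, so cycle maxima rise while minima stay
  put; CPAP-like shifts the whole baseline, leaving the swing unchanged —
  the two signatures the interventions produce in real CVP traces.
* **Doppler**: per beat a half-sine ejection pulse (0.3 s) scaled so the
  beam VTI is exactly `SV · cos(angle) / area` — the closed-form inverse
  of the stroke-volume formula.

What the generator does **not** emulate: realistic arterial/PPG pulse
morphology (dicrotic notch, reflected waves), baroreflex and autonomic
dynamics, vasomotor-tone effects on the PPG, proprietary oximeter
filtering, motion artifacts, ectopy, or any coupling between the rendered
channels beyond the shared beat train and respiratory phase. Passing the
recovery tests therefore demonstrates that the pipeline's numerics are
correct against a clean generative model of the study design — not that
the detectors are robust to every failure mode of clinical recordings.

## Numerical choices

* Canonical channel files print samples with 17 significant digits, so a
  write/read cycle is bit-exact for doubles.
* Zero-phase filtering (Butterworth + forward-backward pass) everywhere a
  peak or trough will be read off afterwards; signals are mirrored about
  their endpoints before filtering because edge transients would
  otherwise distort the first/last respiratory trough.
* Downsampling low-passes at 0.45× the target rate (order 4) and then
  interpolates linearly; the operation is linear and preserves DC
  exactly (the filter runs on the mean-subtracted signal).
* Segment intervals are half-open `[s, e)` so adjacent sequences tile a
  recording; a beat exactly on a cycle boundary belongs to the later
  cycle.
* R-peak detection: band-pass 5–30 Hz, squared derivative, 150 ms moving
  integration, threshold = 8× rolling 2 s median with a 5 %-of-max floor,
  250 ms refractory period, apex refinement on the raw ECG within
  ±100 ms.
* The beat-sampling shortfall of the cycle max/min bounds the dPP
  underestimate by `(1 − cos(π/n))` of the modulation amplitude for `n`
  beats per cycle — with ≥10 beats per cycle under 1 percentage point,
  which is the tolerance the end-to-end tests assert.

## Problem sizes used in validation

The end-to-end recovery experiment uses 6 subjects × LBNP 0/20/40 × PEP
0/5/10 with noiseless channels and 6 breaths/min breathing (~12 beats per
cycle); the statistical recovery experiment refits 200 studies of 20
subjects with the 20/19/13/5 completion pattern at the sequence-truth
level — rendering is bypassed there because the waveform stage's dPP
error is a near-constant multiplicative shortfall, which moves the
intercept, not the slope. These sizes are the package's validation
choices; larger simulations only tighten the same comparisons.

## Known limitations

* The respiratory segmentation assumes one dominant breathing frequency
  per sequence; highly irregular breathing would need a time-varying
  ridge.
* dCVP inherits the cardiac oscillation: the per-cycle max−min includes
  up to twice the cardiac amplitude on top of the respiratory swing, so
  recovered dCVP sits slightly above the pure respiratory target (the
  tests bound this by `2 × cardiac_amp`).
* The automated QC is a stand-in for expert visual inspection; its
  thresholds are configurable and every rejection is logged, but they
  have not been tuned against human-labelled artifacts.
* With few subjects or few completed steps the interaction contrasts are
  weakly identified; the fit flags singular subject-variance estimates
  rather than failing.
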