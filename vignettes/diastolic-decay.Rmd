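---
title: "Comparing aortic and carotid diastolic pressure decay in a virtual arterial population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing aortic and carotid diastolic pressure decay in a virtual arterial population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the model

During diastole the closed aortic valve isolates the arterial tree,
which then behaves approximately as a charged compliance C discharging
through the total peripheral resistance R: pressure relaxes toward the
venous reference with time constant τ = RC. `dpdecay` asks, purely in
silico, whether the decay constant read off the **carotid** pulse agrees
with the one read off the **aortic root** pulse across a wide range of
cardiovascular states — and how robust that agreement is to cuff-based
recalibration of the carotid wave and to additive measurement noise.

Because the package must generate its own data, it implements a reduced
distributed model rather than a full anatomical one:

* **Arterial tree.** 24 segments (aorta in seven tapered pieces, the
  brachiocephalic/carotid/subclavian–brachial branches, splanchnic and
  renal trunks, iliac–leg arteries), each discretized into ≥ 4 lumped
  RLC elements: Poiseuille resistance 8πμl/A², blood inertance ρl/A and
  volume compliance c = D·A·l from the wall distensibility D (1/Pa).
  Local pulse wave velocity follows Bramwell–Hill, pwv = 1/√(ρD), and
  characteristic impedance Z = ρ·pwv/A. Eight terminal beds are
  three-element Windkessels; their resistances are distributed
  inversely with outlet area squared and rescaled — including the
  series viscous path resistance — so the parallel total seen from the
  root equals the subject's TPR exactly. Total compliance is analytic
  bookkeeping: Σ segment c_i (80%) + Σ terminal compliances (20%), and
  per-subject distensibility is rescaled by one solved factor to hit
  the sampled total.
* **Heart.** Time-varying elastance P_lv = E(t)(V − V_d) with a
  double-Hill activation normalized to peak exactly at t_maxE = 340 ms;
  constant-pressure venous filling through a small resistance; aortic
  valve as diode + series resistance + blood-column inertance. The
  valve inertance matters: with an ideal diode, reflected waves
  transiently shut and re-open the valve mid-systole, creating a
  spurious second ejection wave.
* **Wall viscoelasticity.** Each compliance carries a series Voigt
  resistance R_w = τ_w/C (default τ_w = 50 ms, capped at 2 mmHg·s/mL).
  A lossless lumped line rings at its discrete eigenmodes —
  most visibly a weakly damped aorta–leg slosh near 1.5–2 Hz that
  pollutes the diastolic decay of compliant subjects. Wall viscosity is
  the physical damping mechanism of the continuous viscoelastic models
  this package stands in for; it leaves mean pressures untouched.
* **Integration.** Fixed-step RK4 in C++ at ≤ 0.1 ms, with the step
  automatically reduced further whenever the fastest resistive or
  oscillatory pole of a subject's network approaches the explicit
  stability limit. Cycles repeat until the recorded pressures change by
  < 0.01 mmHg cycle-to-cycle (periodic steady state); waveforms are
  emitted at 1 kHz. Identical inputs give bit-identical output.

## The virtual population

Parameters are drawn from truncated Gaussians over stated physiological
ranges (SD = range/4, resample-on-reject): end-systolic and
end-diastolic elastance, filling pressure, heart rate, total arterial
compliance, total peripheral resistance, aortic inlet diameter and
height. Heart rate, compliance and resistance are centered on their
physiological norms (73 bpm, 1.14 mL/mmHg, 1.0 mmHg·s/mL) rather than
on the range midpoints: the ranges are deliberately asymmetric around
the norm (e.g. HR 60–100), and midpoint centering would produce an
accepted population whose means sit visibly off the norms the ranges
were mined around. Other parameters use the midpoint.

Each draw scales the reference tree uniformly: all diameters by
inlet-diameter/3.0 cm, all lengths by height/180 cm, all
distensibilities by one solved factor so the analytic total compliance
equals the sampled value to better than 0.1%.

The plausibility filter compares eight simulated variables (brachial
and aortic SBP, DBP, MAP, PP) against a normotensive and a hypertensive
reference profile and accepts a subject when every variable lies within
mean ± 2.807 SD (a 99.5% normal interval) of at least one profile. The
shipped reference means/SDs are editable approximations of published
population studies of central and peripheral pressure — they are *not*
a reprint of any specific table, and different choices will move the
acceptance fraction. With the defaults, roughly 35–40% of draws are
accepted; draws whose extreme parameter combinations drive any pressure
beyond 400 mmHg fail simulation outright and are counted as rejects.

## The decay estimator

For each accepted subject the aortic-root and left-common-carotid
cycles are re-referenced **foot-to-foot** (rotated to start at the
diastolic minimum) so that diastole runs uninterrupted to the cycle
end; without this the last ~0.1 s of diastole — the best-settled part
of the decay — would be cut off by the activation-phase cycle boundary.
Diastole onset t_in is detected from the aortic valve flow (the start
of the final sustained zero-flow interval); in foot-referenced phase
the carotid shares the same t_in, since the closure wave travels with
the same speed as the foot. A pressure-morphology fallback (earliest
post-peak local minimum of the lightly smoothed trace) serves waveforms
without flow.

Fitting windows cover the last 1/3, last 2/3 or all of diastole,
measured backwards from the cycle end. The mono-exponential
P(t) = P∞ + A·e^(−t/τ) is fit by bounded nonlinear least squares
(`nls` "port", τ ∈ [0.05, 20] s). Two asymptote treatments exist:

* **Fixed venous asymptote (default):** P∞ = 0, the level a two-element
  Windkessel discharge actually relaxes toward. With windows an order
  of magnitude shorter than τ this two-parameter form is the only
  well-identified one. We verified on exact synthetic exponentials that
  a *free*-asymptote fit under σ = 0.3 mmHg sample noise has a τ
  standard deviation of up to ~0.9 s (τ = 3, 1/3 window) — incompatible
  with any claim of noise-robust estimation — while the fixed-asymptote
  fit stays within a few hundredths of a second.
* **Free asymptote (`asymptote = "free"`):** three-parameter fit,
  bounds P∞ ∈ [−50, min(window)] mmHg, log-linear initialization plus a
  deterministic second start at the venous level. On exact
  mono-exponential data it recovers all three parameters to machine
  accuracy; it exists for oracle tests and for data whose asymptote is
  genuinely unknown.

Fits whose τ lands on a bound or whose asymptote hits the −50 mmHg
floor are flagged and excluded pairwise from population statistics;
flag counts are carried in the run metadata.

## Perturbation arms and agreement

The carotid wave enters the comparison in four variants: raw,
cuff-calibrated, and each with additive Gaussian noise
(μ = 0, σ = 0.3 mmHg per sample at 1 kHz; the σ unit is a declared
interpretation — noise on a pressure axis cannot carry seconds).
Calibration min–max normalizes the carotid wave to [0, 1] and rescales
it as p = DBP + k·w with k solved so the cycle mean equals the cuff
MAP = (SBP + 2·DBP)/3, both read from the simulated brachial waveform —
the standard tonometry assumption that DBP and MAP are constant across
large arteries. Note that with a venous-referenced fit, calibration is
*not* a no-op: it shifts the wave's effective floor, which is exactly
why the calibrated arms agree slightly less than the raw ones. Noise is
added after calibration in the calibrated-noisy arms.

Each arm is compared against the noise-free aortic constants of the
matching window: MAE, Pearson r, OLS slope/intercept of carotid on
aortic with a two-sided Wald t-test for zero slope, and Bland–Altman
bias ± 1.96·SD limits of agreement on carotid − aortic (sample SD,
n − 1). The 12-cell grid, per-subject RC table, resolved configuration
and seed are written as plain-text provenance by `run_pipeline()`.

## What the synthetic world does and does not establish

The generator emulates: pulse-wave propagation with physiologic
transit times, peripheral pulse-pressure amplification, diastolic
Windkessel discharge with analytic R and C, cuff-style calibration and
sensor-like additive noise. It does **not** emulate: the anatomical
detail of validated 103-segment models, nonlinear convective effects,
pressure-dependent wall stiffness, non-uniform aortic stiffening with
age, heart-period variability, or realistic tonometry artifacts
(baseline drift, hold-down variation). A green agreement test therefore
establishes that *in a physically reasonable distributed arterial
model* the carotid diastolic decay tracks the aortic one under the
stated perturbations — not that it will do so in vivo.

## Numerical choices

* Periodicity tolerance 0.01 mmHg; minimum 4, maximum 40 cycles.
* Element length 2.5 cm (≥ 4 per segment); halving it changes
  reference-subject SBP by well under 1 mmHg.
* Valve: R = 0.006 mmHg·s/mL, L = 5·10⁻⁴ mmHg·s²/mL.
* Windkessel fixtures integrate the 0-D ODE by RK4 at the same ≤ 0.1 ms
  step, started at the analytic mean pressure so periodicity is reached
  in a few cycles; their diastole is exactly exponential with known RC,
  which is what makes them the estimator's oracle.
* Ties and degeneracies: constant windows are invalid-argument errors;
  windows with fewer than 10 samples are window-too-short errors;
  subjects whose incisura cannot be found are flagged and excluded from
  the affected arm only.
* All randomness descends from one root seed: parameter sampling uses
  it directly, per-subject noise seeds are derived as
  seed + 131071·subject-id (+1 for the calibrated arm), and RNG state
  of the caller is always restored.

## Known limitations

* The reduced tree has 8 terminal beds; real (and full 1-D) models
  distribute runoff over dozens, which damps low-frequency reflection
  modes geometrically. The Voigt wall viscosity compensates but is a
  bulk approximation with one relaxation time.
* Mean fitted τ exceeds the nominal R·C product slightly in compliant
  subjects because early-diastole wave transients and terminal-bed
  redistribution are not pure Windkessel discharge; the windowing
  (last 2/3) mitigates but does not eliminate this.
* The plausibility filter's reference profiles are approximations;
  acceptance fractions and accepted-population means shift with them.
* Brachial "cuff" pressures are read from the simulated brachial
  waveform; no cuff-transfer artifact model is applied.
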