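---
title: "The kicked-Windkessel model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The kicked-Windkessel model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windkick)
```

## The model and its assumptions

`windkick` models the short-term, respiration-driven dynamics of arterial
blood pressure with the smallest structure that can express *selective
buffering*: the observation that respiratory sinus arrhythmia (RSA) can
damp the respiratory fluctuations of one pressure-derived variable (say,
the beat-mean pressure, MAP) while simultaneously amplifying another (the
systolic pressure, SAP).

Three lumped compartments — arterial, cardiopulmonary and venous — hold
blood volume on compliances `C_a`, `C_c`, `C_v` and exchange it through
conductances. Between beats the dynamics are linear apart from one ideal
diode (the valve) gating the venous-to-cardiopulmonary filling:

* arterial runoff `Z_av (p_a - p_v)` — the classical Windkessel discharge;
* diode-gated filling `max(Z_vc (p_v - p_c), 0)`;
* respiratory forcing through the intrathoracic pressure
  `p_I = p0 + p1 (1 + cos 2 pi Phi)`, maximal at inspiration onset
  (integer respiratory phase) and minimal at peak inspiration.

The heart enters only as an impulse pump: an integrate-and-fire phase
`phi` fires a beat at every integer crossing, and the beat transfers the
volume `k * Z_ca * (p_c - p_I)` instantaneously from the cardiopulmonary
to the arterial compartment. Respiration therefore modulates the ejection
*mechanically* (through `p_I` in the gradient) and the heart period
*neurally*: each inspiration onset launches, after a delay `tau`, a
decaying impulse `r0 * exp(-u / tau_n)` that is added to the cardiac phase
velocity, weighted by a phase-effectiveness curve `F(phi mod 1)` (the gain
of a stimulus depends on where in the cardiac cycle it lands; with this
semi-empirical form the gain stays positive, between about 0.49 and 1).

Deliberate simplifications: the respiratory rate is constant; the control
amplitude `r0` is an open-loop constant (no baroreflex closure of the loop
onto pressure); there is no varying-elastance ventricle and no explicit
Frank–Starling law — what filling-time dependence exists emerges from the
`p_c` dynamics; ejection has no valve, so a beat with `p_c < p_I` moves
volume backwards (such beats are counted and reported, and do not occur at
the nominal operating point); inertial effects of blood flow are
neglected. Total blood volume `C_a p_a + C_c p_c + C_v p_v` is exactly
conserved by construction, both by the flows and by the kick.

## Parameters

`wk_params()` is the single source of truth for a run. Units: compliances
ml/mmHg, conductances ml/(s·mmHg), pressures mmHg, rates given in
beats/breaths per minute and stored in cycles/s, times in seconds.

| field | default | meaning |
|---|---|---|
| `C_a`, `C_c`, `C_v` | 1.6, 4.3, 100 | compartment compliances; the venous one is two orders larger, pinning `p_v` nearly constant |
| `Z_vc` | 200 | venous→cardiopulmonary filling conductance |
| `Z_av` | 1.1 | arterial runoff conductance (1/total peripheral resistance) |
| `Z_ca` | 166 | ejection-impulse conductance |
| `p0`, `p1` | −6.6, 1.5 | intrathoracic baseline and respiratory modulation amplitude |
| `r_bpm`, `R_bpm` | 66, 20 | resting heart and respiratory rates |
| `r0` | 0 | neural-control amplitude, cycles/s; negative values slow the heart |
| `tau` | 0.3 | neural delay after inspiration onset, s |
| `tau_n` | 0.3 | neural decay time constant, s |
| `kick_unit_time` | 0.05 | effective ejection-impulse duration `k`, s |

Two defaults deserve their own paragraphs.

**The ejection unit time `k` (0.05 s).** The delta-impulse ejection needs a
dimensional constant converting the conductance–gradient product into a
volume per beat. `k` is that constant, physically the effective duration
of the ejection pulse. It sets the operating point of the whole model: at
`k = 0.05` s the nominal parameter set settles at a mean arterial pressure
of ~122 mmHg, venous pressure ~8 mmHg (slightly above the usual
physiological level), stroke volume ~114 ml and systolic/diastolic values
near 160/90 — a plausible resting human. Values of order 1 s drive the
operating point far outside the physiological range (mean arterial
pressure near 880 mmHg), because per-beat ejections then exceed the volume
the periphery can return in one period, for any admissible initial volume.
50 ms is also the natural reading of an "instantaneous" ejection realised
over one coarse integration step. `k` stays exposed for experimentation.

**The control amplitude `r0` (default 0, reproduction −0.2).** The
buffering analysis defines its own reference state at `r0 = 0`, so the
constructor defaults to control-off and every sweep takes an explicit
amplitude. The packaged reproduction configuration uses `r0 = -0.2`
cycles/s. The choice is anchored on three requirements, not on any target
number: the amplitude must lie on the stable negative branch of the
amplitude response (the positive branch is volatile: fine structure there
reshuffles under small parameter changes); it must produce an RSA of
realistic magnitude (RR-interval standard deviation ≈ 17 ms at the nominal
delay, at the modest end of resting human RSA); and it must be strong
enough that all three relative-fluctuation curves actually cross the 100%
effectiveness threshold, so that effective and ineffective ranges both
exist for SAP, DAP and MAP. Amplitudes below about 0.05 in magnitude fail
the last requirement — the curves hover within a few percent of 100% — and
at |r0| of order 0.01 the control is inert: a per-breath phase kick of
`r0 * tau_n` ≈ 0.003 cycles shifts each beat by ~3 ms, far too little to
touch pressure fluctuations of several mmHg.

## Numerical scheme

* Fixed-step classical Runge–Kutta (RK4), default `dt = 1e-3` s (upper
  bound 5e-3). The system is only mildly stiff (fastest time constant
  `C_c/Z_vc` ≈ 21.5 ms); convergence is verified by the step-halving test
  (beat times move by ~1e-4 s when `dt` is halved, bound 1e-3 s in the
  suite).
* Integer crossings of either phase are located by linear interpolation
  within the step; the step is split at the crossing, the event applied,
  and integration resumed. At most one crossing per step is permitted
  (`dt * dphi/dt < 1`); violation is an error, never silently absorbed.
* At a located beat the cardiac phase is snapped to the integer; the
  time series records both the pre-kick and the post-kick state at the
  exact beat time, so per-beat extrema and the trapezoidal MAP resolve the
  jump without smearing it over a step.
* `phi(0) = 0` does not fire a beat: beats occur at positive integer
  *crossings* only. A beat landing exactly on the final sample may or may
  not be recorded depending on accumulated rounding (at nominal rates a
  40-s run records the boundary beat, a 10-s run does not); statistics use
  complete inter-beat intervals only and are insensitive to this.
* The phase rate is clamped below at zero — a sufficiently strong negative
  kick slows the heart but never runs the phase backwards, which would
  re-fire a beat. Clamped steps are counted and reported.
* The kick sum truncates contributions older than `10 * tau_n`
  (attenuation < e^-10); `Theta(0) = 1` fixes the measure-zero onset
  value for reproducibility.
* Initial state `p_a = 90, p_c = 0, p_v = 9` mmHg, both phases 0. Total
  volume is conserved, so the initial pressures select the operating
  point; these land it in the physiological range.
* Default 40-s runs discard a 10-s transient before any statistic
  (~33 beats of data per run). The transient removes initial-condition
  bias; interval endpoints shift by well under the grid step when it is
  varied.
* Everything is deterministic — there is no randomness anywhere, hence no
  seed argument on any simulation function. Two identical runs are
  byte-identical. CSV output is written with 9 significant digits so
  regenerated fixtures are byte-stable across platforms.

## The buffering analysis

For each per-beat variable (SAP: window maximum of `p_a`; DAP: window
minimum; MAP: trapezoidal time average between consecutive systoles — in
this model systole *is* the kick instant, so windows run from one beat to
the next), the standard deviation across beats measures the total
fluctuation power. The **population** (divisor *N*) convention is fixed
arbitrarily; only like-for-like ratios are ever reported, so the
convention cancels. Relative magnitude = 100 × (controlled std) /
(control-off std), computed against one shared reference per sweep.
Effective-control intervals are maximal contiguous sub-100% runs of the
grid, with interior endpoints refined by linear interpolation across the
100% level; a run touching the grid edge keeps the edge.

At the nominal operating point the delay sweep (`r0 = -0.2`, step 0.02 s)
yields a MAP-effective window of [0.59, 2.11] s with effective SAP control
ending at 1.51 s, strictly inside it. Between those delays lies the
*paradoxical-enhancement* regime: MAP buffered below 100% while SAP
exceeds 100%. The amplitude sweep at the nominal delay (step 5e-4 on
[−0.05, 0.01]) shows a DAP-effective window of [−0.0133, 0), much narrower
than the SAP and MAP windows, confined to the negative branch.

Two structural facts are worth knowing when interpreting fine amplitude
sweeps. First, at the nominal rates the control-off system is exactly
periodic (33 beats = 10 breaths = 30 s), so the response is discontinuous
at `r0 = 0`: an arbitrarily small kick breaks the locking and moves the
statistics by a finite amount. Second, the per-beat statistics are
quantised by the beat count, so relative-magnitude curves carry
sub-percent jitter; interval endpoints are meaningful to roughly the grid
step, not beyond.

## What the deterministic fixtures do and do not show

`generate_fixtures()` writes small canned outputs (beat tables of a
controlled and a control-off 10-s run, a 5-point mini delay sweep)
produced entirely by the model itself; they serve as byte-stable
regression anchors. Like every simulation here they emulate a strictly
periodic respiration, a constant-amplitude intrathoracic modulation and a
noiseless control pathway. Real cardiovascular records have none of these
properties — breathing rate and depth wander, and measurement adds noise —
so green tests certify the internal consistency of the implementation and
the existence of the selective-buffering mechanism in the model, not
quantitative agreement with any particular physiological recording.

## Known limitations

* The nominal filling conductance (`Z_vc = 200`) refills the
  cardiopulmonary compartment within ~20 ms, a small fraction of
  diastole, so stroke volume is nearly insensitive to the RR interval at
  the default operating point; the filling-time pathway only becomes
  influential at much smaller `Z_vc`. The positions of the
  effective-control windows on the delay axis shift by a few tenths of a
  second between those regimes.
* The positive-amplitude branch (`r0 > 0`) is dynamically rich and
  volatile; the package computes it but makes no stability claims there.
* Interval endpoints depend mildly on the (unmodelled) choice of
  transient and on beat-count quantisation, at the scale of the grid
  step.
* The model makes no attempt to reproduce intra-beat waveform morphology;
  there is no dicrotic notch, no pulse-wave propagation, and spectral
  indices of variability are out of scope (with a single fluctuation
  source and a single mechanism, total power suffices).
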