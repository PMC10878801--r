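---
title: "Virtual closed-loop visual stimulation for intermittent locomotion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual closed-loop visual stimulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pausegate)
```

## The experiment being simulated

Marching locust nymphs move intermittently: discrete walking bouts are
separated by pauses, and behavioural evidence suggests the small
directional decisions that hold a swarm together are taken around those
pauses, using visual information about conspecific motion. A
tethered-animal virtual-reality rig probes this directly: the insect
walks on an air-suspended trackball between two screens showing a
random-dot kinematogram (RDK), and a motion sensor on the ball lets the
controller *gate* the stimulus on the animal's own behavioural state.
Three conditions arise:

* **open loop** — dots drift continuously, whatever the animal does;
* **in phase** — dots drift while the animal walks, freeze while it
  pauses;
* **out of phase** — dots freeze while the animal walks, drift while it
  pauses.

Each condition is run with the dots drifting either along the animal's
tethered heading (**forward**) or against it (**backward**). If visual
information is taken up mostly during pauses, direction-dependent
kinematic differences should survive out-of-phase gating and wash out
in-phase.

`pausegate` implements this whole loop virtually: the animal is
replaced by a generative pause-and-go agent, so every downstream stage
— stimulus, gating, path reconstruction, bout metrics, group statistics
— can be exercised and tested without data.

## The stimulus engine

Each of the two virtual screens holds `n_dots_per_screen` point dots
(default 50) on a `screen_width` × `screen_height` cm area (default
30 × 20 cm; the real screens are 30 cm apart and their absolute size
does not enter any kinematic quantity). A fraction `coherence` of the
dots (the SIGNAL dots; default 100%) drift along the screen axis that
corresponds to the agent's heading, at `dot_speed` (default 5 cm/s);
the remainder (NOISE dots) drift the same distance per frame along
fixed, per-dot random directions — the standard RDK noise scheme,
included for generality even though the experiment of interest uses
full coherence. Frames advance at `frame_rate` (default 120 fps).
Positions wrap toroidally; the SIGNAL count is `round(coherence ×
n_dots)` (half-up) and is conserved for the lifetime of the field.

A frozen frame changes nothing but the frame counter, so any number of
inactive frames is an exact no-op on dot positions. Because of that,
whole frame logs can be computed in closed form from the cumulative
count of active frames (`simulate_frames()`), which is what the
stepping function would produce frame by frame — a property the test
suite checks directly. `measure_field_speed()` recovers the realised
dot speed from a log (mean per-frame displacement × frame rate over
non-wrapping steps), which is how the stimulus contract (5 cm/s, 100%
coherence, 120 fps) is verified end to end.

## Motion detection and gating

The rig senses ball displacement, not behaviour. The detector is a
causal hysteresis automaton on per-sample displacement magnitudes:
starting NOT_MOVING, it switches on after `debounce_on` consecutive
samples above `threshold` and off after `debounce_off` consecutive
samples at or below it (defaults: 0.01 cm/sample, 5 and 5 at 120 Hz).
The debounce run-lengths suppress single-sample glitches at the cost of
a bounded latency: detected moving time can differ from true walking
time by at most `(debounce_on + debounce_off) / sample_rate` per bout
transition, a bound the tests assert on noiseless traces.

The gate itself is a truth table: open loop → always active; in phase →
active iff MOVING; out of phase → its exact complement. The controller
acts with a one-sample latency (the sensor sample at `t` gates the
stimulus frame at `t + 1`), mirroring the sensor → controller → display
chain of a real rig. Sensor and display share a single 120 Hz clock;
the real rig's two asynchronous clocks are deliberately collapsed into
one, which removes aliasing effects but none of the feedback structure.

## The pause-and-go agent

The agent embodies three structural facts about locust intermittent
locomotion — walks terminate at random with no memory, pause durations
are heavy-tailed, and directional decisions are taken at pause ends —
plus one hypothesis: visual evidence is weighted by behavioural state,
with pauses dominant.

* **Walk bouts** last Exponential(`tau_w`) (default mean 2 s) and are
  either straight (`WALK_FORWARD`, forward speed `v_walk` = 3 cm/s) or
  turning (`WALK_TURN`, the same forward speed plus yaw at
  `turn_yaw_rate` = 1 rad/s with a per-subject persistent sign).
* **Pauses** follow a bounded power law: baseline hazard
  `h0(t) = (alpha − 1) / (t + t_min)`, giving survival
  `S(t) = (t_min / (t + t_min))^(alpha − 1)`, truncated at `t_max`
  (defaults `t_min` = 0.5 s, `alpha` = 1.8, `t_max` = 60 s; mean
  ≈ 4.0 s, so the resting walking fraction is the renewal ratio
  `tau_w / (tau_w + E[pause])` ≈ 0.33).
* **Evidence** `E` integrates the perceived stimulus leakily:
  `dE/dt = −E / tau_e + w(behaviour) · s · [stimulus active]`, with
  `s = ±1` for forward/backward signal and `w` equal to `w_pause`
  (default 1 s⁻¹) during pauses and `w_walk` (default 0) during walks.
  The default `w_walk = 0` is the sharpest version of the
  pause-weighted-perception hypothesis: walking-phase stimulation
  injects nothing, so an in-phase stimulus should produce (essentially)
  no direction-dependent behaviour.
* **Evidence acts twice.** Evidence *against* the heading (`E < 0`)
  multiplies the pause hazard by `1 + beta · |E|` (default `beta` = 3)
  — the agent cuts pauses short, "hurrying" to rejoin the swarm — and
  raises the probability of starting a turning bout through
  `p_turn = plogis(k_turn · (−E) + b_turn)` (defaults 4 and −2.944,
  i.e. a 5% baseline turn rate). Evidence along the heading never
  lengthens pauses and suppresses turning.

Each trackball channel (forward cm, yaw rad, lateral cm) carries
additive Gaussian sensor noise `sigma` (default 0.002 cm/sample);
ground-truth labels in the trace are noiseless. Trials default to
300 s; published path excerpts are shorter, and no per-animal trial
length is standard, so this is a declared choice giving ≈ 50 bout
cycles per trial.

### Numerical scheme

The loop advances at `dt = 1/sample_rate`. Pause termination uses
hazard thinning (terminate with probability `min(1, h · dt)`), which
matches the target law to first order in `dt`; the standalone sampler
`sample_pause_duration()` inverts the survival function exactly and is
the object of the distributional calibration test (Kolmogorov–Smirnov
distance < 0.01 at 10⁵ draws, including the atom that truncation puts
at `t_max`). Evidence uses forward-Euler, whose fixed point under
constant drive equals the exact steady state `s · w_pause · tau_e`.
Bout clocks accumulate in double precision; the `t_max` cap is applied
with a 10⁻¹² guard. The whole trial loop is implemented natively (C++)
for speed, but the exported single-step R operations define the
semantics: a dedicated test drives them with the identical random-draw
sequence and requires sample-for-sample agreement with the native loop.

## Kinematic analysis

`integrate_path()` dead-reckons the fictive 2D path in a frame fixed to
the initial heading (+x): heading first absorbs the yaw increment, then
the position absorbs the rotated forward/lateral increments. Increments
are consumed as arc lengths in cm, so ball geometry never enters. On a
constant-(v, ω) input the integrator reproduces the analytic circle of
radius v/ω to O(dt), the oracle used in tests.

`segment_bouts()` classifies samples by smoothed speed against
`speed_threshold` (default 0.3 cm/s, 10% of the default walking speed)
and merges interior bouts shorter than `min_bout` (default 0.3 s,
shortest first, coalescing with both neighbours; the first and last
bouts are exempt since the trial truncates them arbitrarily). The
smoothing (default 0.25 s centred window, shrinking at the edges)
averages the forward and lateral *components* and then takes the
magnitude. The order matters: rectifying first would turn zero-mean
sensor noise into a standing Rayleigh speed floor of
`sigma · rate · sqrt(pi/2)` ≈ 0.30 cm/s during pauses — exactly at the
threshold — and walking fraction would be dominated by noise rather
than behaviour. Component-first smoothing cancels the noise instead,
and measured walking fraction then shifts by well under 2% when
default-amplitude noise is added to a clean trace (a regression-tested
bound).

`summarize_kinematics()` reports walking fraction, mean pause duration
(0 with a `no_pause` flag if the trial never pauses), total distance,
total side motion, and path straightness (net displacement over path
length). "Total side motion" has no universal definition on a tethered
rig; here it is `sum(|Δy|)` in the tether frame — lateral progress
perpendicular to the original heading — which makes sustained turning
visible regardless of its direction. An alternative (accumulated |yaw|
× arc length) tracks the same behaviour; the tether-frame form is used
because it is a property of the reconstructed path alone.

Note that segmentation-based metrics are deliberately conservative
relative to ground truth: bouts shorter than `min_bout` are absorbed,
so the segmented mean pause duration weights long pauses more than the
generative mean does. Group *contrasts* are unaffected since every
trial is processed identically.

## Group statistics

`mann_whitney_u()` computes `U = Σ [a_i > b_j] + ½ Σ [a_i = b_j]`
(midrank form) and a two-sided p-value by doubling the smaller
one-sided tail (observed value included), capped at 1. The null is
exact by full enumeration of label assignments when `n_a + n_b ≤ 14`
(ties handled exactly, since enumeration is over the actual pooled
values); a seeded Monte-Carlo permutation null (10⁵ draws, add-one
estimate) when `14 < n ≤ 40` or ties are present; and a tie-corrected
normal approximation with continuity correction beyond that. The method
used is recorded in the output. Permutation draws are taken from the
sorted pooled ranks, so results are invariant to subject ordering. No
multiple-testing correction is applied by default, matching per-panel
testing practice; `correct = "holm"` is available.

With 15 subjects per direction group — the design `run_experiment()`
reproduces — the comparison always takes the permutation path, and its
add-one floor (p ≥ 2/(10⁵+1)) is far below any decision threshold.

## What the generator does and does not establish

The virtual experiment reproduces the qualitative headline pattern by
construction of the agent model: backward stimulation raises walking
fraction, shortens pauses, and increases side motion relative to
forward stimulation in the open-loop and out-of-phase conditions, and
those contrasts are strong at n = 15 per group; in phase, with
`w_walk = 0`, the direction signal is (nearly) absent. Passing tests
therefore validate the *pipeline* — stimulus fidelity, gating logic,
path reconstruction, segmentation, statistics, seeding — not the
biology: the agent is a model of published structural facts, not a fit
to any animal's data.

One consequence of taking the rig seriously is worth stating plainly.
Because detection is debounced and the controller acts with one sample
of latency, an in-phase stimulus keeps drifting for roughly
`(debounce_off + 1)` samples (≈ 50 ms at defaults) into every fresh
pause, and the agent perceives those samples at pause weight. In-phase
gating is therefore an *approximate* null, not an exact one: a small
direction-dependent residual survives in the evidence, of order
`w_pause · (debounce_off + 1)/rate` per pause. The acceptance suite
measures the practical size of this leak as the rejection rate of the
walking-fraction test over 400 replicate in-phase experiments (15 vs
15 subjects, 60 s trials — the duration scaled down from 300 s to keep
the run inside a test-suite budget while leaving dozens of bout cycles
per trial), alongside a companion calibration with `beta = 0`, where
evidence is decoupled from behaviour and the null is exact. The
companion run pins the test's type-I error at its nominal level; the
default-parameter run sits slightly above it, quantifying the leak. A
rig (or model) wanting a sharper in-phase null must shorten detector
latency, not re-tune the statistics.

## Reproducibility machinery

Every random stream descends from one master seed through a splittable
string hash (`derive_seed()`): a trial's seed depends only on (master,
subject, condition, direction), so adding cells or subjects to a design
never perturbs existing trials, and any single trial can be regenerated
in isolation from the experiment manifest (config echo + seeds +
version) that `run_experiment()` writes alongside its CSV outputs.
Within-subject designs draw each subject's persistent traits (turn
sign) and cell order from subject-level streams, then run all cells
back-to-back with independent stimulus seeds.

## Known limitations

* The agent is phenomenological: no biomechanics, no leg kinematics,
  no multi-animal interactions, and its evidence/hazard/turn couplings
  are the simplest forms consistent with the structural facts above.
* Sensor and display share one clock; real rigs have two.
* Dot size, luminance and contrast are not modelled; dots are points
  and the stimulus enters the agent only through its activity flag and
  direction.
* Pause-law parameters put the uncapped mean just inside the
  infinite-mean regime (`alpha < 2`), so trial-level metrics are
  heavy-tailed and trial duration materially affects their variance;
  compare only like-for-like durations.
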