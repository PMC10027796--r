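---
title: "Models, simulators and design choices in vrtrials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulators and design choices in vrtrials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrtrials)
```

`vrtrials` implements a complete, hardware-free behavioral VR experiment:
trial management, frame-locked recording with gaze raycasting, eye-tracker
validation, simulated devices, an example pro-/anti-reach task and the
kinematic analysis of its output. This vignette explains the underlying
models, the parameters that matter, and the design decisions taken where
several defensible options existed.

## Coordinate conventions

All 3D quantities use a right-handed frame with X to the participant's
right, Y up, and Z forward (away from the participant), in meters. Lateral
stimulus offsets are therefore ±X and the reach progresses along +Z.
Orientations are stored as unit quaternions internally and exported as
yaw(Y)–pitch(X)–roll(Z) Euler angles in degrees; quaternions avoid gimbal
problems during computation while Euler angles keep the recorded CSV
human-readable. Handedness is a pure convention: every derived quantity in
the package (angles, distances, velocities, hemifield signs) is invariant
to it, but raw coordinates from engines using a left-handed frame will
differ in sign on one axis.

## The trial data model

A session holds metadata, a global config, an ordered trial list and any
validation results. Each trial carries a 0-based *creation index* and a
1-based *presentation number*: randomization makes the two differ, and both
are needed to relate randomized output back to the designed trial list.
Trial status moves strictly `pending → running → done|error`, and results
can only be written once a trial has started — catching a common class of
bookkeeping bugs in experiment scripts.

Serialization is lossless and double-ended: a single JSON document per
session (the canonical analysis input), plus per-trial and per-sample CSV
tables. CSV import infers column types in the fixed order integer → float
→ boolean literals `true`/`false` → text; this deterministic rule is what
makes `save → load` an identity. In-memory invalid values are `NA`, empty
cells in CSV, and `null` in JSON.

Randomization is seeded and side-effect free (the caller's RNG state is
saved and restored). Within-block shuffling sorts blocks in ascending
numeric order and permutes only within each block; the block sequence is
an invariant checked by the test suite. The session seed is recorded in
the metadata so a whole simulated session is reproducible from one number.

## Recording and raycasting

The simulated frame clock defines time as `frame / rate` seconds with a
default rate of 90 Hz, matching common VR headsets. Recording is strictly
frame-locked — one poll of every registered source per tick. This is
faithful to how display-synchronized recording behaves in practice, and
inherits its known limitation: devices with faster native rates are
down-sampled and may show temporal jitter; the package makes no attempt to
model or correct that.

The gaze ray uses a single combined ("cyclopean") origin between the eyes
rather than per-eye channels. Each frame the tracker-local ray is mapped
through the head pose (origin as a point, direction as a direction) and
intersected with every *pickable* scene object. Visibility and
pickability are deliberately independent flags: the example task records
gaze on an *invisible* fronto-parallel plane while excluding all visible
stimuli from the raycast, so the logged 3D gaze point is always a
well-defined planar coordinate. Intersection uses a 1e-9 m tolerance and
counts grazing (tangent) hits as hits; ties between equally distant
objects resolve by registration order.

A failing device source marks that node's fields invalid for the frame but
never aborts recording — in a real experiment a tracking dropout must not
destroy the trial. Stale gaze data is likewise never allowed to masquerade
as fresh: consumers check that the last gaze was computed on the current
frame.

## Validation metrics

During validation the participant fixates each of five targets — central
and at ±5° horizontally and vertically, all on a sphere of radius equal to
the viewing distance (0.5 m by default) so that eccentricity is purely
angular. Per retained sample the angular error is the angle between the
recorded world gaze direction and the origin→target direction (a scalar
angle, not a 2D screen decomposition). Per target:

* accuracy = mean error, precision = sample SD (n−1), RMSE = root mean
  square (n),

so `RMSE² = accuracy² + ((n−1)/n)·SD²` holds by construction and is
asserted on every computed result. The fixation window is 1 s (90 samples)
with the first 0.2 s discarded as saccade settling; both are configurable
— there is no canonical value, so the defaults are stated here and in the
function documentation. A target with zero valid samples is flagged and
excluded from the (unweighted) across-target averages.

Under the simulator's noise model the error magnitude is Rayleigh: with
per-axis noise σ and no bias, mean error = σ√(π/2) and SD of errors =
σ√((4−π)/2). These closed forms serve as independent oracles in the test
suite (bias recovery at 0.25°/1°/2°, noise recovery at n = 900 samples
within three Monte-Carlo standard errors).

## Device simulators

The simulators exist so every other module is testable headlessly; they
emulate the recording conditions of a small VR reaching study, not
biomechanics.

* **Head**: static pose at eye height (1.2 m, seated) facing +Z, optional
  Gaussian positional jitter.
* **Gaze**: a ray from the cyclopean origin to the current fixation point,
  perturbed first by a constant angular bias and then by per-frame
  Gaussian noise. Offsets are applied about axes orthogonal to the gaze
  direction, so a 1° bias displaces the direction by exactly 1° wherever
  it points. Defaults: noise 0.3°/axis; bias magnitude drawn once per
  participant in 0.2–0.7°, mirroring the accuracy range of consumer VR
  eye trackers. Noise is white (no temporal autocorrelation) — real
  trackers drift and exhibit main-sequence saccade dynamics, which are
  deliberately out of scope.
* **Hand**: rests at a start position (midline, 1.0 m height, 0.05 m
  depth), then follows a straight minimum-jerk path, displacement
  fraction `s(τ) = 10τ³ − 15τ⁴ + 6τ⁵` — the standard smooth-reach model
  with a bell-shaped speed profile peaking at `1.875·D/T`. Per-trial onset
  latency ~ N(0.45, 0.08) s and duration ~ N(0.5, 0.1) s, truncated at
  zero. The reach is scheduled relative to the *expected* go time (cue
  onset + target duration), which is how the early-start mode produces
  onsets before the go cue, exactly as an anticipating participant would.

The reach endpoint's lateral coordinate is the trial's motor goal and its
depth is the proximity plane that ends the trial (0.45 m). With a straight
path, this is the geometry under which the hand's lateral position at the
threshold crossing equals the motor goal, making the noiseless
parameter-recovery properties exact (endpoint error ≈ 0, latency and
duration recovered to within one frame). A reach aimed past the plane
would cross it with a predictable lateral shortfall of
`|goal_x|·(goal_z − 0.45)/(goal_z − start_z)`; users simulating that
scenario can supply their own controller source.

Two scripted "mistake" modes reproduce common data problems: `early_start`
(reach onset centered 0.2 s before the go cue → negative latencies) and
`gaze_to_target` (fixation jumps to the target at its onset → a lateral
step in the gaze-on-plane trace). All draws flow from a single seed; the
same seed yields byte-identical sample streams.

What passing tests on these simulators show — and what they do not: they
verify that the pipeline recovers known ground truth under its own noise
model. They cannot certify performance on real data, which adds tracker
drift, blinks, hand-path curvature, and non-Gaussian noise.

## The example task

Per trial: (1) a white fixation sphere (5 cm diameter) appears at eye
height, 0.5 m ahead; gaze must stay on the sphere for every frame of a
sliding 1 s window — any miss resets the window (no tolerance rule is
standard, so the strictest one is used and documented; a configurable
timeout, default 10 s, turns never-acquired fixation into a trial error).
(2) The sphere recolors — blue for pro, red for anti — while a target cube
appears for 1 s at ±0.30 m from the body midline (operationalized as
x = 0, the head's start position). (3) Both stimuli disappear: this is
the go cue; controller visibility follows the trial's feedback factor.
(4) The trial ends at the first frame with controller depth ≥ 0.45 m,
evaluated on raw per-frame positions without interpolation, mirroring a
per-frame proximity sensor. Every stimulus on/offset and the threshold
crossing are logged as timestamped events.

The design crosses target side × cue × feedback (2×2×2), ten repetitions
each — 80 trials. The derived motor goal is `goal_x = target_x` for pro
and `−target_x` for anti cues. The inter-trial instruction screen of an
interactive experiment is reduced to a logged `trial_start_confirmed`
event, since there is no UI in a headless run.

## Analysis pipeline

Velocity is a backward difference assigned to the later sample, with no
smoothing by default (an optional centered moving average is exposed);
unsmoothed differences keep the onset estimator's bias analyzable. Onset is the first
sample with `v_z` above threshold (default 0.05 m/s, configurable and
recorded in the analysis metadata), searched over the whole trial so that
early starts are found. With the minimum-jerk profile the velocity
criterion fires after an analytic rise lag — the solution of
`(D_z/T)·30τ²(1−τ)² = threshold` — which the tests use as an oracle.

Horizontal endpoint error is computed two ways and both are exported:
against the visual target (`endpoint_error_target`, the literal
definition, which makes a perfect anti-reach score ≈ 0.6 m) and against
the mirrored motor goal (`endpoint_error_goal`, the quantity of interest
for anti trials). The target-referenced value is the default in summary
figures, since it is the measure's plain definition; the goal-referenced
column sits alongside it for analyses that need it.

Outlier filtering removes trials beyond ±k SD (default 3) in latency or
duration. Statistics are computed per participant, pooled across
conditions, in a single pass (no iterative re-computation) — "respective
mean" admits several readings, and the per-participant single-pass rule is
the most conservative and exactly reproducible one. With all values equal
the SD is zero and the band degenerates to the mean, flagging nothing.
Aggregation computes per-participant condition means first, then
across-participant means and standard errors (SD/√N); empty cells are
reported as missing, never as zero.

## Numerical choices and degenerate inputs

* Intersection tolerance 1e-9 m; `t ≥ 0` required; a ray starting inside
  a sphere or box hits the exit surface.
* The minimum-jerk evaluator returns the exact endpoints outside [0, T],
  avoiding floating-point undershoot at the goal.
* Angular distances clamp the normalized dot product into [−1, 1] before
  `acos`.
* Zero-length directions, duplicate node/object ids, non-monotone
  timestamps, and status-transition violations raise immediate errors;
  mid-trial device failures degrade to flagged-invalid samples instead.

## Problem sizes

The packaged tests and the reproduction script run entire simulated
sessions at the study's native size — 80 trials per participant at 90 Hz
(roughly 25,000 samples per session) — plus Monte-Carlo validation runs of
900 retained gaze samples; multi-participant demonstrations in the test
suite use single-repetition (8-trial) sessions, which exercise every code
path at a fraction of the cost.

## Known limitations

No rendering, no real device SDKs, no per-eye gaze channels, no
background high-rate acquisition, no saccade/fixation event detection, and
no statistical inference — the pipeline stops at tidy per-trial measures
and condition aggregates. The simulators are deliberately simple (white
noise, straight reaches, instant saccades); conclusions about real-data
robustness require real data.
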