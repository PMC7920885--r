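---
title: "Methods: bimanual hand-motion analysis for surgical skill assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bimanual hand-motion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handmotion)
```

## Overview

`handmotion` quantifies open-surgery technical skill from overhead video of
an operator wearing colour-coded gloves: green marks the dominant hand,
orange the non-dominant hand. Four stages — colour tracking, 1 Hz
kinematics, Shannon joint entropy, and observational procedure-timing
metrics — are independent and individually testable. A seeded synthetic
generator stands in for surgical footage throughout development and
validation. This vignette records the models, the parameters that matter,
and the design decisions taken where the problem was genuinely open.

## Tracking model

Each frame is segmented per glove with an HSV box (`ColorSpec`): a hue
window in degrees (wrapping through 0/360 is supported), and saturation
and value windows in [0, 1]. HSV was chosen over RGB distance because a
hue window is nearly invariant to the brightness gradients of an operating
field. Connected components of the in-range mask are labelled
(4-connectivity, via `EBImage::bwlabel`) and only the largest component is
kept, which makes the detector robust to small specks and to partially
visible distractor colours. The hand position is the **centre of the
minimal axis-aligned bounding box** of that component — a deliberate,
reproducible convention, not the pixel-mass centroid; the two agree to
sub-pixel level for the compact glove blobs this detector targets.

A detection is valid only if the largest component has at least
`minPixels` pixels; the default is 30 pixels at 1920×1080 and scales with
frame area (floor of 1 pixel). Detection is stateless across frames: frame
*t* depends only on frame *t*. Statelessness is what produces the
observed lock-on behaviour — the tracker re-attaches on the first frame a
glove re-enters the field, and two non-overlapping colour windows can
never swap identities. `trackVideo` refuses colour specifications whose
HSV boxes intersect. Coordinates are pixels, origin top-left, x
rightwards, y downwards; frame indices are 0-based.

Tracks report one record per frame per hand, valid or not, and the gap
list exactly partitions the invalid frames. No smoothing or interpolation
is applied at this stage: the tracker reports what it sees.

## Kinematics at 1 Hz

Hand position is averaged within each second (the mean of valid per-frame
centroids in [k, k+1)); a second is invalid when fewer than half of its
frames have valid detections. Averaging before differencing suppresses
detector pixel noise that differencing at 50 fps would amplify by the
frame rate. From positions p(k) on the 1 Hz grid:

* speed(k) = |p(k+1) − p(k)| in pixels/s,
* acceleration(k) = speed(k+1) − speed(k),
* directional change θ(k) = unsigned angle in [0°, 180°] between
  p(k)→p(k+1) and p(k+1)→p(k+2).

Samples touching an invalid second are invalid. Two further conventions:
θ is undefined (not 0°) when either displacement is exactly zero, because
a still hand has no direction and reporting 0° would fabricate directional
stability; and gaps are never interpolated, because time with the hands
out of the field is meaningful signal in this domain (idle time is itself
a skill metric), not noise to impute. All three series live on the full
grid of `floor(duration)` samples with `NA` marking undefined entries, so
series from different sources always align. Speed and acceleration are
invariant to rotation and translation of the image plane and scale
linearly with pixel rescaling; θ is invariant to all three (verified by
property tests to 1e-9).

## Joint entropy

For each feature, the dominant series X and non-dominant series Y are
paired second by second; a pair is used only when both samples are valid,
and each feature keeps its own maximal valid-pair set (pairwise, not
listwise, filtering). The estimate is the bare plug-in joint entropy in
bits over a shared binning,

H(X,Y) = − Σ p̂(x,y) log₂ p̂(x,y),

with p̂ the joint histogram frequency. No bias correction is applied; the
estimator's upward bias is of order (occupied cells)/(2 n ln 2) and is
part of what the reported value means. The estimate always satisfies
0 ≤ H ≤ 2·log₂(nBins) and H(X,Y) ≤ Ĥ(X)+Ĥ(Y) for the empirical
distribution.

**Binning policy** (the least constrained choice in the method, therefore
fully recorded in every output): direction uses 8 fixed bins of 22.5° over
[0°, 180°]; speed and acceleration use 32 equal-width bins spanning the
1st–99th percentile of the values pooled over both hands, with outliers
clipped into the end bins. This bounds the joint support at 10 bits for
speed/acceleration and 6 bits for direction, the order of magnitude at
which bimanual entropies of this kind are reported. The percentile range
is computed per procedure — no cross-operator calibration exists —
so entropies are comparable across operators only under an identical
binning policy; the realised edges travel with every result. A feature
with zero valid pairs is reported as `NA` with a reason, never as 0
(which would claim perfectly regular motion).

## Procedure-timing metrics

The timeline is a CSV of timestamped events (seconds from video start):
milestones (`skin_incision`, `pectoralis_minor_divided`,
`vessel_loop_passed`), contact intervals (hand or instrument on the
specimen), instrument-out/in intervals (instruments outside the incision),
instrument pickups, and dissection-mode intervals (`blunt`/`sharp`). All
intervals are half-open [start, end). Validation checks the structural
rules (single incision milestone preceding everything, milestone order,
matched and alternating interval events, disjoint dissection modes) and
returns a complete violation list rather than stopping at the first
problem.

Metric definitions: total time runs from incision to vessel-loop passage;
a timeline without the vessel-loop milestone is a procedure not completed
within the time limit (default 1200 s), reported as `completed = FALSE`
with the limit as a "greater than" sentinel. Idle time is the union of
instrument-out intervals; active time is the union of contact intervals,
so simultaneous bimanual activity is not double-counted. Idle and active
derive from different event families and are *not* forced to sum to the
total — the two accountings are independent observations, and observed
panels of such metrics are not additive either. Instrument changes count
transitions between distinct instruments in pickup order; re-picking the
same instrument is not a change. An instrument is considered in use from
its pickup to the next pickup. Ratios with zero denominators are `NA`.
Group summaries report mean and [min, max] per field; censored totals are
excluded from means and counted separately, never averaged silently.

**Numerical choice.** All interval arithmetic runs on an integer
millisecond grid (`round(t·1000)`); sums of annotated durations are then
exact in floating point, which is what makes the generate→recompute round
trip (below) an *exact* equality test rather than a tolerance test.
Millisecond resolution is far below what frame-by-frame human annotation
at 50 fps (20 ms) can distinguish.

## The synthetic generator

The generator is a test harness that emulates the observable structure of
glove-tracking data, not a validated model of human hand motion. A
trajectory (`MotionProfile`) is a constant-speed heading walk: the heading
is piecewise constant and resets at Poisson events
(`directionChangeRate`); each frame step adds isotropic Gaussian jitter
(`jitterSd`, pixels per step); the free path is folded into the frame by
reflection, which keeps generation fully vectorised and deterministic.
Idle bouts — the hand leaving the field, the nearest observable analogue
of instruments resting outside the incision — are placed by exact random
composition so the realised out-of-frame fraction equals `idleFraction`
up to frame quantisation (a two-state Markov switch was rejected: its
occupancy-fraction variance is far too high at 60–100 s durations). The
dominant hand works the left half of the frame and the non-dominant hand
the right half, as two hands flank an incision under an overhead camera;
with the blob radius as margin the rendered blobs can touch but never
occlude one another, so rendered videos are occlusion-free by
construction. All randomness of a call flows from one seed; a fixed seed
reproduces trajectories bit for bit.

Rendering draws solid filled circles (tracking is colour-based; shape and
texture are irrelevant) on a dark background, plus optional distractor
blobs in hue-separable colours, into either a multi-page TIFF (short
clips; frames held in memory) or a PNG frame-sequence directory (constant
memory, any length), with a per-frame ground-truth CSV sidecar.

**Defaults and why.** Frame 320×240 with blob radius 10 px for rendering
tests (small enough to track thousands of frames quickly; `minPixels`
scales down with area). Base speed 400 px/s at UHD scale with one heading
change per 5 s: unhurried gross hand motion under a consumer overhead
camera. The skill presets vary only the jitter ladder and idle fraction —
expert 2 px / 0.03, resident 5 px / 0.06, novice 20 px / 0.08. The jitter
ladder is the skill dial, and its placement is a design requirement of the
generator, not a free choice: with the percentile-adaptive binning above,
binned entropy responds to the *shape* of the speed distribution, which
saturates once the effective 1 Hz jitter scale (≈5.8× the per-step jitter)
approaches the base speed. The defaults put the whole ladder inside the
responsive region, so that mean speed entropy increases strictly from
expert to resident to novice — the qualitative ordering the method must
reproduce — which the acceptance checks verify over 10 seeds of 600 s
trajectories on a 3840×2160 scene.

The timeline generator inverts the metrics: it emits a well-formed
timeline whose computed metrics equal the requested values exactly
(durations on the millisecond grid; bouts separated by at least 1 ms so
start/stop events never collide). Censored procedures are generated by
omitting the vessel-loop milestone and spanning the full time limit.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: lighting variation and colour bleed, motion
blur, occlusion by instruments or the operator's body, glove deformation
(blobs are rigid circles), correlated bimanual coordination (the two
hands are independent), non-stationary skill within a procedure, and any
validated distribution of real surgical hand speeds. Results on real
video depend on glove/lighting calibration of the HSV windows in ways the
synthetic scenes cannot probe.

## Pipeline and reproducibility

`runPipeline` orchestrates both branches per operator from one
configuration (list or YAML/JSON), fails on missing inputs before any
computation, and writes JSON/CSV reports embedding provenance: md5 hashes
of every input, the configuration snapshot, and the package version. No
timestamps are written, so identical inputs give byte-identical reports.
Censored and uncensored aggregates are never mixed. Problem sizes used by
the validation suite — 60 s renders at 320×240 for tracking recovery,
600 s trajectories for entropy ordering, 200-draw metric round trips —
were chosen so the complete suite runs in minutes on a single CPU while
keeping estimator noise well below the effect sizes being checked.

## Limitations

Pixel units only: comparisons across recordings require a standardised
camera geometry. Entropy values are comparable only under an identical
binning policy, and the plug-in estimator's bias ties reported values to
the sample size, which is why every result carries its `n` and bin edges.
The timing metrics require human (or synthetic) event annotation; deriving
events from the tracks themselves is out of scope, as is fine-motor
(finger-level) analysis, which colour-blob tracking cannot resolve.
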