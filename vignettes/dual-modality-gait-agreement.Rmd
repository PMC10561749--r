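---
title: "Dual-modality treadmill gait analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modality treadmill gait analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitagree)
```

`gaitagree` compares two clinically deployable gait-measurement systems on
a treadmill — a single depth camera producing a 30 Hz skeleton stream, and
six 128 Hz inertial measurement units (IMUs) — by computing the same gait
parameters independently from each and quantifying their agreement. This
vignette documents the models, the tunable parameters, what the synthetic
trial generator does and does not emulate, and the design choices made
where the methodological literature leaves the details open.

## Trial model and preprocessing

A trial consists of quiet standing (3 s), a belt ramp, steady walking at
the participant's preferred speed, a belt stop, and standing again. The
three streams carry their own clocks and are *not* synchronized step by
step; the comparison rests on analysing the same wall-clock interval, the
**last 120 s of walking**. The walking segment is found from the belt log
alone: the longest interval with belt speed above 0.2 m/s sustained for at
least 2 s. The threshold and debounce are package choices — any value far
below a plausible preferred walking speed works, and the debounce rejects
logging glitches.

Filtering follows common practice for these devices: IMU channels through
a 4th-order low-pass Butterworth at 10 Hz, skeleton coordinates through a
1st-order low-pass at 6 Hz. Whether such filters are applied single-pass
or forward–backward is often left unstated in methods sections; here the
default is **zero-phase (forward–backward)** application with the stated
order as the per-pass design order, because any phase lag would bias the
cross-modality comparison of event times. Single-pass application is
available via `filter_spec(..., zero_phase = FALSE)`. The implementation
pads with odd reflection so that edge transients decay outside the data
and the DC gain is exactly 1.

All kinematics live in a canonical body frame (X = subject's right,
Y = up, Z = anterior). The depth-camera reader negates all three camera
axes (the subject faces the camera), an isometry that preserves every
inter-joint distance. Tracking dropouts are linearly interpolated up to 3
frames (~100 ms); longer gaps raise an error rather than silently
splitting the recording — pose-estimation dropout of that length usually
indicates occlusion that should be inspected, not bridged.

## Event detection

**Coordinate-based (skeleton).** Per side, the relative anteroposterior
coordinate $r(t) = z_\text{ankle}(t) - z_\text{pelvis}(t)$ peaks when the
foot is most anterior relative to the pelvis (initial contact, IC) and is
most negative at toe-off (TO). Peaks are picked in two passes: a rough
pass estimates the median stride time, a constrained pass enforces a
minimum inter-peak spacing of half that stride time. The ankle (not heel
or toe) drives the detector: it also defines stride length, and heel
tracking is the least reliable of the foot landmarks in this joint set;
the landmark is configurable. The pelvis midpoint serves as the body
reference. Event times are refined to sub-frame precision with a
three-point parabola, and IC/TO alternation is enforced by dropping the
lesser-prominence member of any same-kind adjacent pair.

**Gyroscope-based (foot IMU).** The mediolateral angular velocity of the
foot shows one dominant positive peak per stride at mid-swing. Swing peaks
are selected with a prominence floor of 0.3 × the median swing-peak height
and the same half-stride spacing; IC is the first local minimum after the
peak, TO the last local minimum before it (pre-swing minimum convention —
the TO side of such detectors is known to be the less reliable one). The
peak-finding constants are package defaults, exposed as arguments.

## Gait parameters

Strides are ipsilateral IC-to-IC. Belt-relative spatial quantities add the
**treadmill translation**, the trapezoidal integral of logged belt speed.

* **Kinematic stride length** = Δz of the ankle between consecutive ICs
  plus the belt translation over the stride.
* **Inertial stride length** double-integrates the anteroposterior foot
  acceleration over the swing (TO → following IC) and adds the belt
  translation over that same interval. The initial condition is
  $v(\text{TO}) = -v_\text{belt}$: immediately before toe-off the foot
  still rides the belt. This is the unique reading under which the
  double-integration formula reproduces belt speed × stride time for
  periodic gait; integrating the belt over the full stride instead is
  available behind `belt_interval = "stride"`. Optional dedrifting
  applies a linear correction so the integrated velocity ends at the
  foot's camera-frame landing velocity (0 at the contact instant, just
  before the foot is captured by the belt) — an endpoint-constraint
  analogue of a zero-velocity update that removes accelerometer bias
  accumulated over the swing.
* **Support times** combine bilateral events: single support of a stride
  is the contralateral swing (contralateral TO → IC); double support is
  the sum of the two bilateral-contact intervals. On symmetric gait with
  duty factor $d$ these equal $(1-d)T$ and $(2d-1)T$.
* **Cadence** is bilateral ICs per minute (steps, not strides); the
  operational definition is rarely stated in clinical reports, so
  steps/min is adopted and documented here.
* **Step width** is the mediolateral separation of the two ankle centres
  at each IC (ankle centres, not foot boundaries — systematically wider
  than pressure-based definitions).
* **Margin of stability** uses the extrapolated centre of mass
  $XCoM = CoM + \dot{CoM}/\omega_0$, $\omega_0 = \sqrt{g/l}$ with
  $g = 9.81\,\mathrm{m/s^2}$. The CoM is the pelvis midpoint; its velocity
  comes from central differences on the filtered pelvis track (one-sided
  at the edges). The pendulum length $l$ defaults to the participant's
  leg length and falls back to the mean IC-time ankle-to-pelvis distance.
  The mediolateral bound is the leading **ankle** (consistent with the
  step-width definition), the anteroposterior bound the leading **toe**;
  signs are positive when the XCoM lies inside the base of support. With
  zero CoM velocity the margin reduces exactly to the geometric distance.
* **Arm swing (IMU)** integrates the wrist gyroscope about the first
  principal axis of its covariance; cycles run between successive upward
  zero crossings of the projected rate, the angle is linearly dedrifted
  per cycle, and the amplitude is its peak-to-peak range. **Arm swing
  (skeleton)** applies the cosine theorem to the chord between successive
  extreme wrist positions about the shoulder; chords beyond the diameter
  (noise) are clamped and flagged. Position noise *inflates* chord
  lengths, so the kinematic arm swing is biased slightly high — the test
  suite checks this bias against a Monte-Carlo chord-inflation oracle.

Window summaries average every parameter over all strides in the window,
pooling sides (arm swing within side), with stride counts recorded.

## Agreement statistics

Differences are taken as **IMU − kinematic** throughout. Per parameter:
Shapiro–Wilk normality per method; a two-sided paired t-test (degenerate
zero-variance differences are reported explicitly rather than producing
NaN); Pearson correlation when both margins pass normality at α = 0.05,
Spearman otherwise, with the choice recorded; and Bland–Altman limits of
agreement, mean difference ± multiplier × SD (n − 1 denominator). The
**multiplier defaults to 1.96**, not 2.0: published limits in this
literature consistently match 1.96 × SD even when figure captions say
"doubled standard deviation". It is a configurable argument. No
multiple-testing correction is applied (single α = 0.05), matching
standard practice in method-comparison studies; interpret the per-
parameter p-values accordingly.

## The synthetic trial generator

No recorded trials ship with this package, so validation rests on a
kinematic stick-walker with analytic ground truth. Per stride, the stance
foot rides the belt (camera-frame velocity $-v_\text{belt}$); the swing
foot returns along a **quintic** whose boundary conditions match position,
velocity and acceleration to the belt at toe-off and land the ankle at a
fixed home station. Stride-time jitter is truncated-Gaussian with a
configurable coefficient of variation; because every swing re-lands at the
home station, the walker holds its station on the belt and the true
stride length is exactly the belt translation over the stride. The pelvis
(CoM proxy) sways mediolaterally at stride frequency and bounces
vertically at twice stride frequency; wrists swing about fixed shoulders
in the sagittal plane, anti-phase to the ipsilateral leg; the foot pitch
rate is a stylized waveform with a dominant positive mid-swing peak and
sharp negative dips at TO and IC. IMU channels are analytic derivatives of
these trajectories, world-aligned and gravity-free (the `IDEALIZED`
sensor mode); `imu_sensor_frame()` adds gravity and rotates channels by a
pitch profile for `REALISTIC` sensor-frame tests. Gaussian measurement
noise is added per stream (defaults: 3 mm skeleton joints, 25 mm wrists,
0.05 m/s² accelerometer, 0.01 rad/s gyroscope — the reported accuracy
scale of these devices).

One boundary condition deserves a note. The swing's landing velocity is
**zero in the camera frame** at the contact instant, with the jump to
$-v_\text{belt}$ occurring on the stance side of the boundary (a
heel-strike impact). A fully smooth landing at $-v_\text{belt}$ would be
kinder to the accelerometer model, but it would place the maximum of the
ankle-minus-pelvis coordinate 50–80 ms *before* the true contact,
contaminating the coordinate-based detector by more than two frames on
perfectly clean data. With the impact model the coordinate maximum
coincides with the true IC, while the double-integration identity is
untouched (only the toe-off initial condition enters it). A side effect
is faithful to real systems: the coordinate-based **toe-off** is detected
tens of milliseconds late (the ankle keeps moving belt-ward after the
true TO), so support times disagree between modalities on synthetic data
much as they do in practice.

Default profile values (belt 1.05 m/s, stride time 1.1 s, duty factor
0.60, step width 0.12 m, ML sway 0.03 m, arm swing 40° peak-to-peak) are
configuration anchored in ranges typical for community-dwelling older
adults, not claims about any population. The generator is a test harness:
it emulates steady-state treadmill walking with standing bookends, known
events and known per-stride parameters. It does **not** emulate
pose-estimation artefacts (identity switches, occlusion, depth noise that
is structured rather than Gaussian), soft-tissue artefact, sensor
orientation drift, turning, stops, or pathological gait. Passing the
recovery suite therefore demonstrates correctness of the algorithms under
their stated assumptions — not device accuracy on real patients.

## Numerical choices

* Zero-phase filtering with odd-reflection padding (above).
* Integrals (belt translation, velocity, displacement, gyro angle) are
  trapezoidal on the native sample grid with exact interval endpoints
  interpolated in.
* Peak positions are refined by a three-point parabola, clamped to
  ±half a sample.
* Alternation repair drops the lesser-prominence event of a same-kind
  pair; ties keep the earlier event.
* A contralateral toe-off coinciding exactly with a stride's own IC
  (duty factor 0.5) is attributed to that stride through a 1 ns
  tolerance, so double support degrades continuously to zero at the
  walking/running boundary.
* Strides missing their own toe-off keep stride time and length but are
  excluded from support times and inertial stride length (fields NA, not
  zero).

## Problem sizes used by the validation suite

The test suite and the acceptance script run noise-free trials of 126 s
of walking (a 120 s analysis window, ~110 strides per side) over a
3 × 3 grid of stride times {0.9, 1.1, 1.3} s × belt speeds
{0.7, 1.0, 1.3} m/s, one noisy trial at the default profile, and
cohort-level agreement on 54 synthetic participants with 1000 replicate
difference cohorts for the limits-of-agreement exceedance rate. These
sizes give sub-millimetre Monte-Carlo error on window means while keeping
a full run in the order of a minute.

## Known limitations

* Real-device inertial processing assumes pre-rotated, gravity-free
  anteroposterior acceleration; free orientation fusion from raw sensor
  frames is out of scope (`imu_sensor_frame()` covers only the
  simulator's known pitch profile).
* The margin of stability inherits the pelvis-midpoint CoM
  approximation; values are not comparable to full-body CoM models, and
  the anteroposterior margin depends strongly on where the walker stands
  on the belt.
* Support times inherit the toe-off bias of the coordinate-based
  detector (by design, see above); between-modality comparisons of
  these parameters are informative about the method, not about the
  walker.
* Agreement statistics treat participants as independent and identically
  processed; repeated-measures and regression-based limits of agreement
  are out of scope.
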