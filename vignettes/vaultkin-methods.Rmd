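---
title: "Methods: run-up and take-off kinematics and two-method agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: run-up and take-off kinematics and two-method agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaultkin)
```

## The problem

Field studies of elite pole vaulting compare two ways of obtaining the same
kinematics from multi-camera video of the final run-up steps and take-off: a
manually digitised reference (REF) and an automated markerless alternative
(ML). vaultkin implements the full measurement chain for that comparison —
DLT reconstruction, filtering, a segmental centre-of-mass (CM) model, event
detection, a 22-variable run-up/take-off set, and an agreement battery — plus
a synthetic vaulter generator so that every stage can be tested without any
real capture data (none are publicly deposited for this kind of competition
study).

The global frame is fixed throughout: X along the runway toward the plant
box, Z vertical (up), Y mediolateral completing a right-handed frame, with
the runway plane at Z = 0. All quantities are in metres, m/s and degrees.

## Reconstruction: 11-parameter DLT

Each camera is a standard 11-coefficient direct linear transformation
(`dlt_calibrate()`), solved in least squares from at least six non-coplanar
control points. The linear system is normalised (control points and pixels
centred and scaled) purely for conditioning; coefficients are mapped back to
the original units, so the normalisation is convention-free. No lens
distortion terms are fitted: the synthetic cameras are ideal pinholes and no
distortion model is available for the real rig. Points are triangulated by
least-squares intersection of the DLT ray equations over all cameras that see
them (`dlt_reconstruct()`); two views suffice, and frames with fewer than two
views are flagged missing, never fabricated. A condition number of the
triangulation system is kept as a geometry diagnostic. Calibration reports an
RMS reprojection residual in pixels per camera, and an object-space RMS
residual over the control points reconstructed from the whole rig
(`dlt_calibrate_rig()`).

## Filtering and differentiation

Landmark coordinates are low-pass filtered with a second-order Butterworth at
20 Hz (100 Hz capture), applied forward and backward for zero phase lag
(`butterworth_lowpass()`). Two documented choices:

* **No dual-pass cutoff correction.** The stated cutoff is the design cutoff
  of the single-pass filter, which is common biomechanics practice; the dual
  pass therefore attenuates slightly more at the cutoff than -3 dB. Users who
  want a corrected cutoff can pass an adjusted value in `series_spec()`.
* **Coordinate-level filtering.** The filter is applied to the raw landmark
  coordinates before any derived quantity (CM, angles, velocities), so both
  methods are processed identically at the signal level. Ten padding frames
  at each end of the digitised sequence absorb filter initialisation; the
  implementation additionally uses odd-reflection padding internally sized
  from the filter's pole radius, so a constant series passes through exactly.

Velocities are central differences of the filtered signals (one-sided at the
series ends), with no sub-frame interpolation at events: at 100 Hz a
one-frame read is the native resolution of the data.

## Segmental model

The whole-body CM is the mass-fraction-weighted sum of segment CMs, each
placed at `proximal + cm_ratio * (distal - proximal)` along its landmark
axis, using the adjusted de Leva body-segment inertial parameters by sex
(`segmental_table()`). On the 17 tracked landmarks (head centre; left/right
shoulder, elbow, wrist, MCP, hip, knee, ankle, MTP) the segments are: head
(point mass at the head centre), trunk (mid-shoulder to mid-hip), and paired
upper arms, forearms, hands (wrist to MCP), thighs, shanks and feet. Because
no heel is tracked, the foot axis is ankle-to-MTP and the foot CM ratio is
re-based to 0.5 of that axis. Printed mass fractions sum to 0.9999 for the
female table (rounding in the source); the table is renormalised so fractions
sum to one exactly, which the tests assert.

Joint angles are measured in the sagittal (X–Z) projection, at the joint,
with the conventions of the run-up/take-off literature: hip = 180° plus the
signed angle between the downward trunk extension and the thigh (forward
flexion < 180°, hyperextension > 180°, no wrap-around — take-off-leg hips
read near 195°); knee = 180° minus the included thigh–shank angle (180° in
standing); ankle = the included angle between the ankle-to-knee and
ankle-to-MTP vectors (90° in standing, 120–135° plantar-flexed at toe-off).
The ankle convention deserves a note: measuring between the *axis* directions
(knee-to-ankle vs ankle-to-MTP) also gives 90° in standing but collapses to
~30° at toe-off, contradicting the published magnitudes, so the at-joint form
is used. Angles assume progression toward +X; a trial digitised in the
opposite direction should be mirrored first.

## Events and variables

Ground contact of a toe (MTP) is defined by height below 2 cm AND horizontal
speed below 0.8 m/s, where speed is the smaller of the forward and backward
one-sided differences so that both the touchdown frame and the toe-off frame
count as contact. The mask is cleaned morphologically (gaps of up to 2 frames
bridged, contacts shorter than 3 frames dropped) to be robust to
millimetre-level landmark noise. Toe-off is the last frame of a contact,
touchdown the first; the last four toe-offs define the analysed window.
Detection runs on *unfiltered* toe trajectories: the 20 Hz filter rounds the
contact corner and can move contact edges by a frame, whereas the raw corner
is unambiguous. The pole is not tracked, so the pole-plant frame is supplied
(from config or the generator's ground truth).

The 22 discrete variables (`variable_catalogue()`) follow the standard
definitions: toe-off-to-toe-off step lengths measured on the departing foot's
MTP in X; step velocities as CM X displacement divided by the step duration —
the exact time-average of the instantaneous velocity, chosen over a frame-wise
mean of the differentiated signal because the discrete frame mean carries an
O(1/n) window-edge bias (the two are identical under constant velocity);
average runway velocity over the last three steps in the same form, and
maximum runway velocity as the maximum instantaneous CM X velocity in that
window; CM height and instantaneous velocities at pole plant and take-off
("standing height" is, per the conventional definition, the CM height at
take-off — alias `take_off_cm_height`); take-off angle `atan2(vz, vx)`; and
absolute take-off velocity including the mediolateral component. Joint angles
of the take-off leg (TOL, the last leg in contact) and drive leg (DL) are
sampled at the take-off frame.

Waveforms (CM displacement and velocity, six joint angles) are sliced from
the touchdown of the third-last step to take-off; both methods always share
the identical frame window per trial (events are detected once, on the
reference). A 101-point time-normalised copy is emitted for group-mean
plotting only — all statistics use the native frames.

## Agreement battery

With differences `d = REF - ML` per trial: bias = mean(d); random error =
1.96 × sample SD of d (n−1 denominator); limits of agreement = bias ± random
error. Bias and LOA are computed from inputs rounded to 3 decimals, matching
the convention of reporting LOA from data at that precision; RMSE
(`sqrt(mean(d^2))`, which satisfies `rmse² = bias² + population variance of
d`) and ICC use full precision. ICC(3,1) is the two-way mixed, single-measure,
consistency form `(MS_rows − MS_error) / (MS_rows + MS_error)`, computed from
explicit sums of squares (residual SS taken directly from the two-way
residuals for numerical stability) and cross-checked in the tests against
`stats::aov`. Waveform similarity is the CMD: the R² of a simple linear
regression of the alternative waveform on the reference, which is symmetric
in its arguments and blind to amplitude (`cmd(x, a*x + b) = 1`). ICC and CMD
are banded poor/moderate/good/excellent at 0.50/0.75/0.90 with boundary
values assigned upward. Heatmap values are the per-variable mean ML − REF
difference, i.e. the negated bias, following the convention that warm colours
mean the alternative over-estimates. Whether the underlying SD convention of
published tables uses n or n−1 cannot be decided from printed values; n−1 is
used.

## The synthetic vaulter

`generate_trial()` builds a kinematically consistent 17-landmark trial from a
prescribed CM path plus articulated limbs. It is a kinematic generator — no
forces, no pole mechanics, no flight phase beyond a short projectile tail —
because the pipeline under test consumes trajectories only.

* **CM path.** Per-step constant mean horizontal velocity with per-step
  durations `T_k = s_k / v_k` (so step lengths and mean velocities are exact
  by construction), a linear deceleration through the final stance to a
  take-off horizontal velocity (default 8.0 m/s men, 6.9 women) that
  preserves the exact last-step mean, a sinusoidal vertical oscillation
  phase-locked to mid-stances, and a constant-acceleration vertical rise from
  pole plant to take-off reaching the launch velocity (2.70/2.26 m/s). The
  rise through the plant stands in for pole support.
* **Limbs.** Feet are anchored at contact positions spaced by the exact step
  lengths, swing on smooth profiles between contacts, and sweep forward and
  up after their final stance (knee drive). Legs are solved by two-link
  inverse kinematics with the knee anterior; the stance foot pitch rises over
  the anchored toe and is adjusted in closed form when the leg could not
  otherwise reach. The pelvis is placed each frame by a damped fixed-point
  iteration so that the de Leva whole-body CM of the assembled posture equals
  the prescribed CM path to ~1e-12 m.
* **Ground truth.** Step lengths and mean velocities equal the parameters to
  1e-9; event-instant velocities are the central differences of the
  closed-form CM profile at the event frames — the same estimator the
  pipeline applies — so extraction on the noise-free trial reproduces the
  ground truth to better than 1e-6 with filtering off. Events are exact by
  construction and the rule-based detector recovers them exactly on clean
  data and within ±1 frame under 2 mm landmark noise.
* **Method degradation.** `degrade_as_method()` applies per-landmark
  systematic shifts then isotropic Gaussian noise, emulating the
  landmark-identification discrepancies of a markerless tracker (defaults:
  millimetre-scale anterior/superior shifts largest at distal joints, 3 mm
  noise for ML vs 1 mm for REF).
* **Cameras.** Four roof-mounted 2048×1536 px pinholes covering the last
  12–15 m of the runway; landmarks outside a frame are flagged, not clipped,
  and control points for calibration span the capture volume.

Defaults for each sex were calibrated once against the published elite group
tables shipped with the package (`published_group_means()`): runway
velocities near 9.63/8.30 m/s, step lengths 1.8–2.2 m, CM height at pole
plant near 1.12/1.06 m. With these defaults every male ground-truth variable
falls inside the published mean ± 3 SD envelope; for women all CM and spatial
variables do, while the take-off-leg knee (147° vs a published 166.5° ± 2.1°)
sits outside a band whose 2.1° SD is far tighter than a schematic limb model
can be expected to match. The generator's angle *profiles* are plausible
gait shapes driven by inverse kinematics, not fits to published angle data —
conclusions about joint-angle agreement on real data should rest on the
statistics engine (which is tested against oracles), not on the realism of
the synthetic knees. Jittered athlete draws in `run_comparison()` are
rejection-sampled to kinematic feasibility, so extreme parameter combinations
are re-drawn rather than producing an inconsistent skeleton.

What the generator deliberately does not emulate: mediolateral CM motion
(Y ≡ 0, so the mediolateral CMD is undefined on synthetic data and flagged),
soft-tissue and digitising drift, camera synchronisation error, lens
distortion, runway camber (a perfect plane is assumed) and the airborne
phase. Passing tests on synthetic data therefore validate the measurement
chain and the statistics, not the biological realism of any individual
waveform.

## Numerical choices and degenerate inputs

* Fixed-point CM placement: damping 0.9, tolerance 1e-12 m, hard failure
  above 1e-8 (reported as a configuration error).
* Contact detection thresholds: 2 cm height, 0.8 m/s speed; cleaning with
  3-frame minimum contacts and 2-frame gap bridging. All exposed as
  arguments.
* Zero-variance waveforms (e.g. a constant channel) make CMD undefined: the
  value is `NA` with a warning, never coerced to 0 or 1. Zero between-trial
  variance likewise makes ICC undefined and flagged.
* Coplanar control points, points behind a camera, fewer than two views,
  fewer than four detected toe-offs, events outside the trajectory window,
  and mismatched trial sets all raise structured errors naming the offending
  frames, landmarks or variables.
* Filter preconditions: series must exceed `3 × order + 2 × pad_frames`
  samples.

## Problem sizes used in the shipped checks

The packaged test-and-acceptance workloads run at sizes a laptop handles in
about a minute: eight-trial comparisons (four men, four women, mirroring the
published cohort), 100-point geometry round trips at three pixel-noise
levels, 200 random tables for the ICC oracle, and 100 replicate eight-trial
batches for bias recovery. These sizes give Monte-Carlo standard errors well
below the tolerances asserted and can be scaled up freely via the exported
functions.

## Known limitations

Single-plant-box geometry (no curved approach), no pole or upper-body
contact modelling, point-mass head, no inertia tensors or angular momentum,
consistency-form ICC only (no absolute-agreement variant), and no
mixed-effects agreement models. The retest report pairs waveform frames (and
the three step lengths) rather than replicate whole trials, matching the
single-sequence re-digitising protocol it supports.
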