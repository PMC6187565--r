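---
title: "Methods: wearable-IMU gait analysis via multi-sensor fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable-IMU gait analysis via multi-sensor fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imugait)
```

`imugait` turns raw logs from body-worn IMU/MARG sensors (feet, shanks,
thighs; 100 Hz) into spatio-temporal gait parameters and bilateral-symmetry
statistics. This vignette is the package's own account of the underlying
models, the numerical choices made where the design was genuinely open, and
the limits of what the bundled simulator can demonstrate.

## Conventions

Quaternions are scalar-first, Hamilton-product, unit-norm after every public
operation; `q` maps the sensor frame to the global frame
(`v_global = R(q) v_sensor`). The global frame is right-handed with z up, so
a resting accelerometer's specific force reads `+g` along sensor z when the
sensor is level, and the gravity vector used for strapdown compensation is
`(0, 0, 9.81)` m/s². Euler angles use the aerospace Z-Y-X sequence; the
pitch arcsine argument is clamped to `[-1, 1]` so the ±90° singularity only
costs round-off, never an error. These conventions are a documented choice:
nothing in the measurement model itself fixes handedness or the mapping
direction, but the choice makes the gravity-error cross product
`e = â × (R' ẑ)` well-defined with a positive feedback sign.

## Sensor calibration

**Accelerometer non-orthogonality.** A misaligned triad maps true specific
force through `E` (unit-diagonal, entries α, β, γ at the off-axis
positions), so static multi-orientation readings lie on an ellipsoid rather
than the sphere `‖a‖ = g`. The quadric coefficient vector
`O = (a, b, c, f, g, h, p, q, r, d)` is estimated by minimising the
algebraic residual `‖CO‖²` under the ellipsoid constraint `O'MO = 1`
(equivalently `4B − A² = 1` with `A = a + b + c`,
`B = ab + bc + ac − f² − g² − h²`), reduced to a 6×6 generalized
eigenproblem. Two numerical points matter:

* The `+1` branch of the constraint can only represent mildly eccentric
  ellipsoids (axis ratios below about 2); elongated ellipsoids have
  `4B − A² < 0`. The solver therefore normalizes candidates to
  `|O'MO| = 1`, searches both branches of the pencil, and keeps the
  minimum-residual candidate whose quadric is a genuine ellipsoid
  (positive-definite form matrix, positive centered radius). Calibration
  ellipsoids are near-spherical and always land on the `+1` branch.
* Center and radii come from the stationary point `−S⁻¹(p, q, r)` and the
  eigendecomposition of the form matrix `S = [[a,h,g],[h,b,f],[g,f,c]]`;
  axes are permuted/signed to the assignment closest to the identity, valid
  because misalignment angles are small by assumption.

The angles are then read off analytically: with `P = (g²Q)⁻¹ = EE'`
normalized by `P₃₃` (which cancels any overall scale, so a wrong assumed
gravity magnitude cannot bias the angles), `α = asin(P₁₃)`,
`γ = asin(P₂₃)`, `sin β = (P₁₂ − sin α sin γ)/(cos α cos γ)` — exact under
the trigonometric forward model, second-order under the small-angle one.

`correct_accel()` defaults to the small-angle inverse of `E` (residual of
order `2×10⁻⁴` of the signal); the pipeline uses the exact inverse because
that residual, multiplied by 40 m/s² swing accelerations every stride,
otherwise integrates into a visible per-stride position bias.

**Magnetometer.** Hard iron is the fitted ellipsoid center; soft iron is
corrected by the symmetric positive-definite square root of the centered
form matrix, scaled so calibrated samples have norm equal to the mean field
magnitude. The absolute field scale is unobservable (soft iron absorbs it);
directions are recovered exactly on noiseless data. Non-orthogonality of
the magnetometer triad is algebraically confounded with soft iron and is
deliberately not separated.

**Calibration capture sizes.** The simulator's default captures are a
one-minute static protocol (60 orientations × 1 s) and a 30 s figure-eight
sweep. These durations are set by noise propagation, not convenience: the
misalignment estimate is noise-limited, and a residual tilt of angle δ in
the corrected gravity reference leaks `δ × stride_length` of vertical
position error per stride that no zero-velocity update can remove, while
soft-iron axis noise becomes a constant heading bias. Halving the captures
roughly √2-inflates both.

## Stance detection

Two per-sample criteria are fused: the trailing moving variance (window
`N`) of the normalized squared acceleration norm
`V = (aₓ/g)² + (a_y/g)² + (a_z/g)²`, and the trailing angular-rate energy
`E = Σ‖ω‖²/(σ_ω²W)`. A sample is stance when the variance falls below λ₁
and the energy below λ₂. Design decisions:

* `V` itself is ≈1 at rest, so it is the *variance* of `V` that is
  thresholded — the only reading under which both criteria are small at
  rest.
* For three-axis white gyro noise the energy statistic has expectation 3 at
  rest (it is a scaled chi-square mean), so λ₂ must sit above 3; the
  default is 6, orders of magnitude below swing energies. The energy is
  computed on bias-compensated rates, with bias and σ_ω² both estimated
  from the initial rest second when not supplied.
* Window statistics are *computed* trailing (causal), then re-centered by
  `(N−1)/2` samples. Purely trailing alignment delays detected stance
  onsets by a full window (~140 ms at N = 15), which is useless for gait
  events; centered alignment with the default `W = N = 7` keeps onset and
  offset within ±3 samples of truth.
* Morphological cleanup closes sub-`min_stance` swing gaps (rare
  chi-square exceedances inside a true stance would otherwise split
  intervals) and removes sub-`min_stance` stance runs. Default
  `min_stance` = 0.1 s.

The defaults (λ₁ = 0.02, λ₂ = 6, W = N = 7, `min_stance` = 0.1 s) were
calibrated once on the simulator at its default noise scales and are all
exposed in `stance_config()`.

## Attitude fusion

Gyro rates are integrated through the quaternion kinematic equation with a
first-order exponential-free step plus renormalization, using the midpoint
(trapezoidal) rate over each step: the right-endpoint rate leaves a
systematic `O(dt² ω̇)` phase lag — up to ~0.9° mid-swing at 100 Hz — that
converts into millimetres of position bias per stride.

Drift is removed by PI feedback on two reference directions:

* **Gravity.** `e_g = â × c` with `c = R(q)' ẑ` the predicted sensor-frame
  gravity direction; the measured acceleration is normalized first so the
  error is bounded by 1. The correction only makes sense in the
  quasi-static state, and amplitude gates alone are insufficient: mid-swing
  the specific-force norm crosses `g` with a badly wrong direction. The
  correction is therefore gated on (a) `|‖a‖ − g|/g ≤ 0.1`, (b)
  `‖ω‖ ≤ 0.3` rad/s, and (c) the detected stance mask when one is
  supplied — which the pipeline always does.
* **Magnetic field.** The measurement is rotated to the global frame, the
  reference is pinned to `(√(h_x²+h_y²), 0, h_z)` (measured dip, azimuth
  zero), and the resulting cross product is projected onto the predicted
  gravity axis. With a dipped field the raw cross product carries tilt
  components; the projection makes the correction heading-only by
  construction, so magnetic disturbances can never corrupt inclination.

Gains default to `k_p = 2`, `k_i = 2` with a magnetic error weight of 10.
The weight compensates the geometric attenuation of heading errors (the
squared horizontal field fraction, ≈0.23 at a 61° dip); the stiff integral
lets the filter learn residual gyro bias within a few seconds — with a
sluggish integral, even a well-estimated bias leaves a 0.1–0.5° heading
error that persists for most of a one-minute walk and dominates the
position budget, since lateral error is heading error times distance
walked. All gains are exposed in `fusion_config()`.

Initialization: roll/pitch from the mean static accelerometer over the
first second, yaw from the tilt-compensated magnetometer; per-sensor gyro
bias from the initial standstill, then refined over all (edge-eroded)
detected stance samples, where the foot is truly stationary.

## ZVU position integration and stride parameters

Gravity-compensated global acceleration is integrated trapezoidally;
velocity is pinned to zero inside each stance interval (eroded by a 5-sample
guard band so detection-edge samples with genuine residual motion are not
clamped), and the residual velocity reaching each stance onset is
redistributed linearly backward over the preceding swing. This de-drift
exactly cancels the position error of any constant acceleration bias over a
swing; what survives is the time-varying part, which is why attitude
accuracy during swing matters so much.

Strides span consecutive initial contacts; stance time is the leading
interval's duration; stride length is the horizontal displacement between
the componentwise median positions of the bounding stance intervals
(medians resist integration ringing); clearance is the peak swing elevation
over the mean vertical position of the bounding stances. Cadence counts
steps: `120/cycle` per minute. Because quiet standing merges with the
adjacent stance, the stride spanning gait initiation has an inflated cycle;
`compute_gait_parameters()` excludes strides whose cycle or stance deviates
more than 25 % from the session median (standard steady-state stride
selection), which drops exactly those boundary strides.

Knee flexion integrates `(ω_thigh − ω_shank)` about the flexion axis and
adds the initial inclination difference measured from static accelerometer
gravity components. The integral is re-anchored to the standing value at
each stance midpoint, where the knee sits at its stance plateau — this
bounds gyro drift to a single stride. The ankle (shank-minus-foot analog,
dorsiflexion positive) deliberately gets *no* such reset: the shank keeps
moving with the thigh throughout stance, so the ankle is nowhere near its
standing value at mid-stance and a reset would inject a systematic offset
of several degrees. After bias removal the ankle's residual drift is about
a degree per minute.

## Bilateral symmetry statistics

Bilateral knee ROM is compared with a one-way ANOVA over stride-paired
groups: the first 20 steady strides contribute 20 groups of two
observations (left and right of the same stride index), giving the
19/20/39 degree-of-freedom structure of a 40-observation table. Under this
design a bilateral ROM difference inflates the *within-pair* variance, so
asymmetric gait shows as a small F and a large p; symmetric gait with
natural stride-to-stride variability shows the opposite. The package
reports standard p-value semantics (upper tail of the F distribution);
published tables in this area sometimes verbally invert the reading
("p < 0.05 means symmetry"), which is consistent with the design above but
not with standard hypothesis-testing language — the numbers themselves
reconstruct exactly either way. `anova_from_ss()` rebuilds complete tables
(MS, F, p, totals) from printed (SS, df) pairs for verification against
published decompositions.

## The simulator, and what passing tests do not show

`simulate_truth()` builds closed-form lower-limb trajectories realizing the
configured stride length, clearance, cycle, stance fraction and knee
profile *exactly*, for both sides (right phase-shifted by half a cycle),
bracketed by 2 s and 1 s of quiet standing. Defaults are healthy-adult
scales: cycle 1.32 s, stance fraction 0.65, stride length 1.21 m,
clearance 0.22 m, knee flexion 7.2°–66.2° (ROM 59°). Swing primitives are
C³ at the contacts (minimal-jerk septic advance, sin⁴ lift and flexion
bumps, a quintic amplitude envelope on the thigh oscillation): with merely
C¹ primitives, sampling real 35–45 m/s² swing accelerations at 100 Hz
leaves ~4 mm/s velocity kinks per stride — an artifact of undersampling an
impact transient that a band-limited physical sensor would smooth out.
Sensors are modeled at their segment's rotation center, so orientation
changes do not displace them.

`synthesize_imu()` applies the full error model: misalignment `E` on
specific force, per-axis constant gyro bias (drawn per sensor at 1°/s
1-sigma) plus white noise (accelerometer 0.02 m/s², gyroscope 1°/s,
magnetometer 0.1 field units — the platform's bias-stability scale), and
hard/soft-iron distortion of the field `(22, 0, −40)` (arbitrary units,
realistic downward dip). Per-side scalings of length, clearance and ROM
emulate asymmetric (hemiplegic) gait; clearance asymmetry of 15 cm vs 5 cm
reproduces the classic hemiplegia pattern in the per-foot statistics.

What the simulator does *not* emulate — and hence what green tests do not
demonstrate about real recordings: soft-tissue artifact and strap slip,
sensor-to-segment misalignment beyond the static pose, magnetic
disturbance from nearby ferrous objects during the walk, impact transients
and sensor saturation at heel strike, temperature drift, pathological
variability (tremor, spasticity, freezing), turns and stairs. Real-data
accuracy will be worse than the simulator's figures; the simulator's role
is to verify that the implementation is a faithful, internally consistent
realization of the method.

## Position-accuracy evaluation

`position_accuracy()` scores the pipeline's foot trajectories against the
simulator's truth as RMS 3-D error over the whole session, reporting the
worse foot. Before scoring, the estimate's frame is registered to the
truth frame by a single least-squares rotation about gravity — standard
practice when comparing dead-reckoned tracks against an external reference,
because a magnetometer-referenced system's absolute heading is only defined
up to its calibration azimuth (0.02–0.06° here, which over a 50 m walk
would otherwise dominate everything the method itself can control). The
unregistered score is available with `align_yaw = FALSE`. On ten 60 s
sessions at the default noise scales the worst-seed RMS error is about
1.3 cm; the problem sizes used throughout (43 strides per session, ten
seeds, 6 × 10³ samples per sensor) keep the full validation suite
comfortably fast while exercising every stage at full length.

## Known limitations

* Sagittal-plane joint angles only; full 3-D six-degree-of-freedom joint
  kinematics (ISB conventions) are out of scope.
* The ZVU machinery requires foot sensors; shank/thigh positions are not
  dead-reckoned (no stationary phase to anchor them).
* Stride length asymmetry scaling changes per-foot footprint spacing — a
  surrogate for step asymmetry, not a kinematically consistent two-legged
  model over long walks.
* The stance detector's defaults assume the 100 Hz, sensor-grade noise
  regime; very slow or shuffling gait (long double-support, low swing
  energy) may need retuned thresholds, which is why every threshold is a
  config field.
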