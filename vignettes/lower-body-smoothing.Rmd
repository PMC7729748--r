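---
title: "Magnetometer-free lower-body motion capture by factor-graph smoothing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetometer-free lower-body motion capture by factor-graph smoothing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imumocap)
```

## The estimation problem

Seven inertial measurement units are strapped to the lower body: lumbar
(sacrum), both thighs, both shanks, and both feet, numbered 1--7 in that
order. Each IMU measures its body-frame angular velocity and specific force
at 200 Hz, corrupted by slowly varying biases and white noise. Where the
IMUs sit on each segment -- their orientation and position relative to the
underlying bone -- is unknown, and no magnetometer or other heading
reference is available.

The package estimates, in a single batch maximum a posteriori (MAP)
problem:

* the pose (orientation and position), velocity, instantaneous angular
  velocity, and 6-dim sensor bias of every IMU at every *keyframe* (by
  default every 20th sample, i.e. 10 Hz);
* four static unit vectors on the sphere: the knee hinge axis expressed in
  the right/left thigh and shank IMU frames;
* twelve static IMU-to-joint-center offset vectors (lumbar to each hip;
  thigh to hip and knee; shank to knee and ankle; foot to ankle).

From these it derives anatomical femur/tibia coordinate systems in the ISB
convention (z proximal, y anterior, x to the subject's right) and the
knee's flexion/extension, internal/external rotation and ab/adduction
angles via the Grood--Suntay joint coordinate system.

## The factor graph

The posterior factors into per-keyframe measurement terms and static
priors; MAP estimation minimizes the sum of squared Mahalanobis residuals.
Per keyframe interval and IMU, a *preintegration* factor summarizes the 20
raw samples into one relative-motion constraint (rotation, velocity,
position deltas with a 9x9 propagated covariance and first-order bias
Jacobians), and a *bias random-walk* factor ties consecutive biases. Per
keyframe there are:

* an *angular velocity* factor per IMU tying the estimated body rate to the
  raw gyro sample coinciding with the keyframe (the first sample of each
  decimation block);
* four *hinge* factors: the relative angular velocity across each knee,
  expressed in the proximal frame, must be parallel to the static axis; the
  residual is its component orthogonal to the axis. The same constraint is
  repeated with the arguments swapped for the axis in the distal frame;
* six *joint-center* factors: the two offset vectors flanking each hip,
  knee and ankle, pushed through the current poses, must name the same
  navigation-frame point.

Static factors appear once: four axis--segment angle priors (the knee axis
is not orthogonal to the femur/tibia proximal direction; the packaged
means/stds are 84/2.4, 92/1.2, 96/2.4 and 88/1.2 degrees for the right
femur, right tibia, left femur and left tibia), five anthropometric length
priors (femur and tibia per leg, femoral head separation), five
continuously differentiable min/max window penalties, and two cross-leg
length discrepancy priors (0.8 cm femur, 0.6 cm tibia). A formulation that
repeats the static factors at every keyframe merely rescales their weight
with trajectory length; replicate it, if desired, by dividing the prior
stds by `sqrt(M)`.

The total tangent dimension is `126 M + 44` for `M` keyframes: 18 per IMU
per keyframe (3 rotation, 3 position, 3 velocity, 3 angular velocity, 6
bias) and 44 static (4 axes with 2-dim sphere tangents, 12 offsets).

## On-manifold optimization

States live on products of SO(3), R^3 and S^2. The solver is
Levenberg--Marquardt in tangent coordinates: the whitened Jacobian is
assembled sparsely (compiled code), the damped normal equations are solved
by sparse Cholesky factorization with a fill-reducing ordering (CHOLMOD;
only the diagonal shift is refactored when the damping changes), and steps
are applied through retractions -- rotation updates by the exponential map
with re-orthonormalization, axis updates along great circles in a
deterministic tangent basis built from the axis's largest-magnitude
component. Pose tangents order rotation first, then translation; the
translation retraction is additive.

Convergence follows the usual criteria for this problem class: absolute
error change at or below `1e-6`, relative change at or below `1e-4`, or
10,000 iterations. Damping starts at `1e-5`, multiplied by 10 on a
rejected step and divided by 10 on acceptance. On the synthetic datasets
below, convergence from the trivial initialization takes 7--15 iterations
(a few seconds at M = 301, under a minute at M = 601 on one core).

Initialization is deliberately trivial: identity orientations, zero
positions, velocities, angular velocities and biases, and a nominal
skeleton alignment (axes along IMU x; offsets 0.2 m along IMU z toward the
adjacent joints, hip offsets (+-0.09, 0, -0.1) m from the lumbar IMU, 0.1 m
foot-to-ankle offsets).

## Identifiability, gauge freedoms, and anchoring

Without absolute references, the solution is invariant to a global
translation, a constant velocity offset, and a rotation about gravity.
These are anchored by priors of zero position, zero velocity and zero
heading on the first lumbar keyframe; heading is a 1-DOF residual on the
yaw of a Z-Y-X Euler decomposition. Weak priors (0.02 rad/s, 0.1 m/s^2)
are placed on the initial biases.

One further flat mode deserves emphasis because first-keyframe anchors do
*not* remove it: a global tilt `G` about a horizontal axis, combined with a
velocity drift `(g - Gg) t` and position drift `(g - Gg) t^2 / 2`, leaves
every measurement factor exactly invariant -- the accelerometer terms
transform covariantly, and all inter-IMU constraints are relative. The
package verifies this invariance numerically in its test suite. Left
unpinned, an optimizer iterating to tight tolerances performs a random walk
along this valley while fitting noise, and pitch/roll accuracy degrades
with iteration count. `add_gauge_priors()` therefore also places a weak
zero-mean *bounded-speed* prior (std 2 m/s, generous for sacrum speeds in a
standing calibration protocol) on the lumbar velocity at every keyframe,
which pins the tilt to a fraction of a millidegree while penalizing
physically plausible velocities negligibly.

Two practical nonidentifiabilities remain properties of the data, not the
implementation. A motionless subject leaves the axes and offsets
unidentified (the hinge residual's axis Jacobian vanishes with the relative
angular velocity); the test suite confirms the normal matrix develops a
null space concentrated on the static block for a static scene. And the
knee center is only localized along the medial/lateral hinge line by the
axis--segment angle priors, so its recovery there is prior-limited: with
population priors the MAP knee center can legitimately sit a few
centimeters from a subject's true one when the subject's axis--segment
angle deviates from the population mean. With subject-calibrated priors
(`calibrated_priors()`, the precisely-measured-anthropometry mode) this
bias disappears. The hip-adjacent offsets are the least identified overall
-- lumbar excitation is modest and its joint-center vectors point mostly
along gravity -- and the lumbar--thigh distance errors are accordingly
several times larger than for the other pairs, a pattern reported for this
class of estimator on real data as well.

Both signs of each knee axis solve the hinge model equally well, giving
four equivalent minima per leg. `disambiguate_axes()` resolves them
post hoc: if the median navigation-frame angle between a knee's two axes
exceeds 90 degrees, the distal axis is flipped; if the median flexion angle
then exceeds +20 degrees, both axes are flipped (the ISB-convention knee
range of motion is roughly +10 to -150 degrees, so a predominantly positive
flexion trace indicates left-pointing axes). A median inter-axis angle at
exactly 90 degrees is genuinely ambiguous and raises an error rather than
guessing. The procedure is idempotent. The +20-degree median rule
presumes the knee spends a meaningful fraction of the recording flexed; on
a trace dominated by upright standing the median sits near zero under
either sign and the second step cannot discriminate -- if in doubt, feed
the disambiguation a flexion-rich segment.

## Noise model and parameter defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `sigma_w` | 0.005 | rad/s/sqrt(Hz) | gyro white-noise density |
| `sigma_a` | 0.05 | m/s^2/sqrt(Hz) | accelerometer white-noise density |
| `sigma_bw_g`, `sigma_bw_a` | 1e-4 | unit/sqrt(s) | bias random-walk densities |
| `Sigma_g` | (0.005 rad/s)^2 I | -- | keyframe angular-velocity residual |
| `Sigma_K` | (0.05 rad/s)^2 I | -- | hinge residual |
| `Sigma_j` | (0.01 m)^2 I | -- | joint-center residual |
| `a` | 100 | 1/m | window-penalty sharpness |
| `g` | (0, 0, -9.81) | m/s^2 | gravity, z-up navigation frame |

Discrete-time white noise relates to the densities by `sigma / sqrt(dt)`.
In simulation studies the residual covariances should be set consistently
with the injected noise -- in particular `Sigma_g` should be the
*discrete* gyro noise `sigma_w^2 / dt`, and `Sigma_K`/`Sigma_j` should
absorb the soft-tissue perturbation actually applied (the validation suite
uses 0.1 rad/s and 0.01 m with 5 mm artifact). On real data these two
covariances are best fit empirically from a reference capture via
`fit_noise_covariance()`, which returns the maximum-likelihood zero-mean
Gaussian covariance; all residual models here are zero-mean by
construction. The `arccos` argument in the axis--segment model is clamped
to [-1, 1] (clamping beyond 1e-9 is reported), and composite
male/female population priors combine as mean `(mu_M + mu_F)/2` and
variance `sigma_M^2 + sigma_F^2`, exactly as tabulated sources are merged.

## The synthetic-data generator

Because no public dataset accompanies this estimation problem, the package
ships a first-class simulator. `make_skeleton()` draws segment lengths
inside the anthropometric windows, cross-leg discrepancies from their
population stds, and axis--segment angles from the per-side priors; the
hinge axis is realized *geometrically*: it is elevated from the leg's
transverse axis by `90 - theta_femur` degrees so its angle with the
hip--knee line is exactly the sampled femur value, and the knee--ankle line
is bent by `theta_tibia - theta_femur` (the tibiofemoral angle, about 8
degrees at the prior means) so the tibia angle holds too. IMU mounting
poses are randomized in height and around the limb circumference, with
mounting tilts up to 20 degrees -- approximate strapping, not calibration.

`script_motion_profile()` orders the excitation routine -- per-ankle
flexion cycles and foot circles, per-knee flexion swings of at least 90
degrees, per-hip flexion, ab/adduction and rotation, then torso bend,
twist, and side bend -- as fifteen equal windows with three repetitions of
each joint primitive. All joint-angle signals are built from quintic
smoothstep bumps, which are C^2, so angular velocity and angular
acceleration exist analytically; the chain rule for composed rotations
propagates them exactly through pelvis -> hip -> knee -> ankle, and a small
C^2 pelvis sway keeps the root excited throughout. Consequently
joint-center coherence holds to machine precision and the relative angular
velocity across each knee is exactly parallel to the true axis -- the
generator's ground truth drives every residual in the model to zero.

`synthesize_imu()` applies the sensor model. Its default `"discrete"` mode
emits the exact inter-sample rates `Log(R_k^T R_(k+1)) / dt` and velocity
differences, a valid discretization of the continuous model under which
the package's first-order integrator reproduces the truth *exactly* in the
noise-free limit; `"sampled"` mode emits instantaneous rates instead, whose
first-order integration error at 200 Hz is comparable to sensor-grade
noise. Noise-free recovery statements in the tests rely on the discrete
mode. `perturb_soft_tissue()` adds a zero-mean sinusoidal translation
(and optionally rotation) of each IMU's mounting pose, updated analytically
so the perturbed trajectory remains a self-consistent rigid motion; what it
breaks, deliberately, is the static-offset and static-axis assumption.

What the generator does not emulate: genuinely aperiodic soft-tissue
dynamics correlated with muscle activation, imperfect (non-hinge) knee
kinematics such as tibiofemoral translation, magnetometer disturbances
(irrelevant here), sensor dropouts, and temperature-dependent bias drift.
Passing the validation suite therefore demonstrates correctness of the
estimator under its own modeling assumptions plus bounded artifact -- not
performance on any particular human cohort.

## Validation studies and the sizes used

The packaged tests and the acceptance script re-run these studies from
scratch:

* *Preintegration equivalence*: 100 random 20-sample windows; state
  prediction through the compound delta matches sequential integration to
  1e-9, and the propagated 9x9 covariance matches a 1200-draw Monte-Carlo
  within 15% per diagonal entry.
* *Hinge-axis recovery*: 30 s of knee-only motion at 200 Hz; the axis
  calibrator recovers the true axis to under 0.1 degree noise-free and
  under 2 degrees at gyro noise 0.005 rad/s/sqrt(Hz).
* *Joint-center recovery*: 30 s of fully excited hip motion; offsets to
  under 1 mm noise-free (the problem is linear least squares given poses)
  and under 1 cm with 1-degree/5-mm pose perturbations.
* *End-to-end*: 60 s full profile at 200 Hz, keyframes at 10 Hz (M = 601,
  tangent dimension 75,770), sensor noise and 5 mm soft-tissue artifact,
  trivial initialization and population priors: knee flexion RMSE under 5
  degrees, pitch/roll RMSE under 2 degrees per IMU, mean inter-IMU
  distance RMSE under 5 cm.
* *Structure*: gauge invariances before anchoring and their removal after;
  disambiguation from all four sign combinations; Grood--Suntay round
  trips over a grid including +-150 degrees flexion; factor counts and the
  `126 M + 44` dimension accounting.

A 30-s dataset at decimation 40 (M = 151) is used for the noise-free
recovery study to keep the default test run fast; the conclusions are
unchanged at finer keyframing.

## Worked example

```{r example, eval = FALSE}
library(imumocap)

noise <- noise_spec(sigma_g = 0.005 / sqrt(1 / 200),
                    sigma_K = 0.1, sigma_j = 0.01)
sim <- simulate_dataset(duration = 60, seed = 11, noise = noise,
                        noisy = TRUE, soft_tissue_mm = 5)
sol <- estimate_lower_body(sim$streams, noise = noise)
ang <- derive_knee_angles(sol)
ev <- evaluate_solution(sol, sim$truth)
round(ev$knee_flexion_rmse, 2)
round(range(ang$right$flexion))
```

## Known limitations

The estimator inherits the model's assumptions: static axes and offsets
(soft tissue enters only as noise), ideal hinge knees, Gaussian isotropic
residuals. Population anthropometric priors bias the knee center's
medial/lateral placement for subjects far from the population mean --
measure the subject when that matters. The lumbar-to-hip offsets are the
least observable parameters; interpret hip-adjacent position output
accordingly. The trivial initialization has a basin of attraction that
covers the simulated conditions here, but local minima are a known hazard
of this problem class on less exciting motion. Hip and ankle angles are
not derived; the anatomical machinery stops at the knee.
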