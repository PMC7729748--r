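# imumocap

Magnetometer-free, self-calibrating lower-body inertial motion capture in R.

Seven body-worn IMUs (lumbar, both thighs, shanks and feet) measure angular
velocity and specific force; where each IMU sits on its segment is unknown,
and indoors there is no reliable heading reference. `imumocap` estimates the
full IMU pose/velocity/bias trajectories **jointly** with a static
biomechanical map — the knee hinge axes `r ∈ S²` expressed in the thigh and
shank IMU frames, and the twelve IMU-to-joint-center offset vectors
`s ∈ R³` — by maximum a posteriori smoothing over a factor graph, then
derives ISB-convention knee angles (Grood–Suntay joint coordinate system).
No functional calibration poses, no magnetometers, no prior sensor
alignment.

## The model

The MAP problem minimizes a sum of squared Mahalanobis residuals
`Σ ‖e‖²_Σ` over:

* **IMU preintegration** — per keyframe interval, the raw 200 Hz samples are
  compounded into one relative-motion constraint `(ΔR, Δv, Δp)` with a
  propagated 9×9 covariance and first-order bias Jacobians, plus a bias
  random-walk factor `e = b_j − b_i`;
* **keyframe angular velocity** — `e = ω̂ + b_ω − ω̃`;
* **knee pseudo-hinge** — the relative angular velocity across the knee,
  `m = Rᵀ_A R_B ω̂_B − ω̂_A`, must be parallel to the static axis:
  `e = m − (m·r) r`, repeated with swapped arguments for the distal frame;
* **constrained joint centers** — `e = X_A(s_Aj) − X_B(s_Bj)` for the two
  offsets flanking each hip, knee and ankle;
* **anthropometry** — axis–segment angle priors
  `e = μ − arccos(r·(s₁−s₂)/‖s₁−s₂‖)`, segment-length priors
  `e = ‖s₁−s₂‖ − μ_L`, smooth min/max window penalties
  `(x−x_max)·tanh²(a(x−x_max))`, and right/left length-discrepancy priors.

Optimization is on-manifold Levenberg–Marquardt (SO(3) exponential
retractions, 2-DOF sphere charts for the axes) with a sparse Cholesky
solve; gauge freedoms (global position, velocity, heading — and a subtler
tilt-with-velocity-drift mode, see the vignette) are anchored by priors.
A first-class synthetic-data module simulates the whole system — a
kinematic chain with C² joint-angle scripts, analytic angular
velocity/acceleration, randomized IMU mounting, sensor noise and
soft-tissue artifact — so every claim is testable against known ground
truth.

## Worked example

```r
library(imumocap)

# study conditions: 60 s calibration profile, 200 Hz, sensor noise,
# 5 mm soft-tissue artifact; residual covariances consistent with the noise
noise <- noise_spec(sigma_g = 0.005 / sqrt(1 / 200),
                    sigma_K = 0.1, sigma_j = 0.01)
sim <- simulate_dataset(duration = 60, seed = 11, noise = noise,
                        noisy = TRUE, soft_tissue_mm = 5)

sol <- estimate_lower_body(sim$streams, noise = noise)   # ~15 s, one core
sol
#> lower-body IMU solution: 601 keyframes, 75770 tangent dims
#>   total error 4017.82 | termination rel_tol | 8 iterations

ang <- derive_knee_angles(sol)          # disambiguated, ISB convention
round(range(ang$right$flexion))
#> [1] -92   2

ev <- evaluate_solution(sol, sim$truth)
round(ev$knee_flexion_rmse, 2)          # degrees, right / left knee
#>  right   left
#>   0.99   2.88
round(mean(ev$distance_rmse_cm), 2)     # mean inter-IMU distance RMSE, cm
#> [1] 1.19
```

The flexion trace spans standing (≈0°) to deep flexion (≈−92°,
ISB-negative); sub-5° flexion RMSE against ground truth is recovered from a
trivial initialization (identity orientations, zero positions, nominal
skeleton), with the hinge axes found to within ~1–2° and pitch/roll to
within ~0.5°. Lumbar-to-hip offsets are the least observable parameters
and dominate the residual position error, mirroring what is reported for
this estimator class on real data.

A thin CLI wraps the same functions
(`inst/scripts/imumocap simulate|estimate|angles|evaluate`); see
`?run_cli`.

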