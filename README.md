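# imugait

Wearable inertial-sensor gait analysis via multi-sensor fusion, in R.

Quantitative gait analysis — stride length, speed, cadence, stance/swing
times, foot clearance, knee range of motion (ROM) and their bilateral
symmetry — is routinely needed for rehabilitation assessment of patients
with gait impairments (stroke hemiplegia, arthropathy), but optical motion
capture is expensive and confined to a lab. Body-worn IMU/MARG sensors
(tri-axial accelerometer + gyroscope + magnetometer) strapped to the feet,
shanks and thighs are a portable alternative, provided the raw streams are
carefully calibrated, fused and integrated. `imugait` implements that whole
chain and ships a parametric gait simulator that generates ground-truth
kinematics and realistic raw sensor streams, so every stage is validated
end to end.

## What it computes

1. **Sensor calibration by constrained ellipsoid fitting.** Static
   multi-orientation accelerometer readings lie on an ellipsoid
   `x'Qx = 1` whose shape encodes the triad's non-orthogonality; the
   quadric `ax² + by² + cz² + 2fyz + 2gxz + 2hxy + 2px + 2qy + 2rz + d = 0`
   is fitted by minimising `‖CO‖²` subject to `O'MO = 1` (the
   `4B − A² = 1` ellipsoid constraint), solved as a generalized
   eigenproblem `C'C O = λMO`. The misalignment angles (α, β, γ) follow
   analytically from `E E' = (g²Q)⁻¹`. The same fit calibrates the
   magnetometer's hard-iron offset (ellipsoid center) and soft-iron
   distortion (symmetric square root of the form matrix) from a
   figure-eight sweep.
2. **Attitude by a PI complementary filter.** The quaternion kinematic
   equation `q̇ = ½ Ω(ω) q` is integrated at 100 Hz; gravity and magnetic
   reference directions steer the rates through cross-product error
   vectors with proportional-integral feedback
   `ω ← ω + k_p e + k_i ∫e dτ`, gated to quasi-static samples.
3. **ZVU dead reckoning.** Stance is detected per sample from the moving
   variance of `V = (a_x/g)² + (a_y/g)² + (a_z/g)²` and the normalized
   angular-rate energy `E = Σ‖ω‖²/(σ_ω²W)` (`V`-variance < λ₁ AND
   `E` < λ₂); gravity-compensated acceleration is double-integrated with
   velocity pinned to zero in stance and per-stride de-drifting
   (zero-velocity updates).
4. **Gait parameters and symmetry statistics.** Strides are segmented at
   initial contacts; knee flexion comes from
   `θ_knee = ∫(ω_thigh − ω_shank)dt + θ_thigh0 − θ_shank0`; per-stride
   parameters are summarized as mean ± SD and bilateral knee ROM is
   compared with a stride-paired one-way ANOVA (Source/SS/df/MS/F/p
   layout).

## Worked example

```r
library(imugait)

# a 60 s walk: 43 strides/foot, healthy-adult scales, sensor-grade noise
session <- simulate_session(gait_config(n_strides = 43, seed = 1),
                            sensor_error_model(seed = 1))
report <- run_pipeline(session)
report$parameters$L
#> gait parameters over 42 strides (mean +/- SD):
#>   stride_length       1.210 +/- 0.001
#>   stride_speed        0.916 +/- 0.004
#>   stride_frequency   90.894 +/- 0.387
#>   walking_cycle       1.320 +/- 0.006
#>   stance_time         0.825 +/- 0.006
#>   swing_time          0.495 +/- 0.006
#>   clearance           0.219 +/- 0.000
#>   knee_rom           59.065 +/- 0.132

position_accuracy(session, report = report)$worst
#> [1] 0.008772844
```

The left-foot summary recovers the simulator's configured gait (stride
length 1.21 m, cycle 1.32 s, clearance 0.22 m, knee ROM 59°) to within a
fraction of a percent, and the worst-foot RMS 3-D position error over the
whole minute of walking is below a centimetre for this seed (about
1.3 cm for the worst of ten seeds). `report$anova` holds the
bilateral knee-ROM ANOVA; `write_gait_report(report, "out/")` exports
per-stride CSVs, the summary table and a JSON report.

A thin command-line wrapper covers the same flow from a shell:

```sh
Rscript inst/cli/imugait.R simulate --out session/ --strides 20 --seed 7
Rscript inst/cli/imugait.R run --in session/ --out report/
```

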