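# hipforce

Hip contact force (HCF) prediction from gait by inverse dynamics and
static-optimization muscle recruitment — an open, tested implementation of
the full marker-to-contact-force pipeline used in lower-limb
musculoskeletal modelling, with the diagnostic tooling that makes faulty
muscle geometry visible.

It is written for biomechanists and musculoskeletal modellers who want the
complete chain in one auditable package:

* **Rigid-body model**: segment tree with ball/hinge joints, floating-base
  pelvis, patella coupler, skin-marker protocol, anthropometric scaling
  (per-segment length scales, mass redistribution, length–mass–fat muscle
  strength scaling), Harrington hip-joint-centre regression.
* **Kinematics**: zero-phase low-pass filtering, marker/segment-length
  calibration against a trial, per-frame weighted least-squares inverse
  kinematics.
* **Muscle geometry**: via points, single-cylinder wrapping with explicit
  side convention (closed-form tangent–geodesic–tangent lengths),
  tendon-excursion moment arms, moment-arm sweeps with discontinuity
  flagging.
* **Dynamics and recruitment**: recursive Newton–Euler net joint loads,
  then per-frame muscle forces minimizing the sum of cubed activations
  subject to moment equilibrium and non-negativity, solved through the
  exact KKT conditions.
* **Contact force and diagnosis**: the limb free-body balance

  `HCF + F_inertial + F_gravity + GRF + Σᵢ Fᵢ = 0`,

  where `Fᵢ = fᵢ ûᵢ` is each hip-crossing element's force along its line of
  action; per-muscle/per-group decomposition of the HCF and joint moments;
  heuristic flags for elements with disproportionate contributions;
  component/total/stance/swing RMSE and activation on–off timing against
  reference measurements.
* **Synthetic gait**: a generator producing full trials (Fourier joint
  profiles, forward-kinematics markers, double-bump GRF calibrated to a
  body-weight cycle average, self-consistent reference HCF) and a
  three-entry toy model catalogue, so everything is testable without
  external data.

## Worked example

```r
library(hipforce)

model <- make_toy_model("lowerlimb-12m")
model
#> <skeletal_model> 'lowerlimb-12m'
#>   segments: 4  joints: 3  muscles: 12  markers: 13
#>   dofs: 11  root: pelvis  subject: 78 kg / 1.72 m

trial <- generate_gait_trial(model, gait_params(seed = 1))
res <- run_pipeline(model, trial)

cat(sprintf("max limb-balance closure residual: %.2e BW\n",
            max(res$closure_residual_bw)))
#> max limb-balance closure residual: 4.94e-15 BW
res$validation
#> <validation_report>
#>   RMSE total: 0.000 BW (stance 0.000, swing 0.000)
#>   RMSE components AP/ML/PD: 0.000 / 0.000 / 0.000 BW
#>   peaks: first 25.57 vs 25.57 BW, second 19.85 vs 19.85 BW
```

The closure residual is the per-frame norm of the limb free-body balance —
machine precision, because the contact force, the free-body terms, and the
per-muscle decomposition are held to the same identity through two
independent computation routes.  The RMSE report is zero here because the
trial's "measured" HCF is the generator's self-consistent reference and the
pipeline reproduces it exactly on noise-free input.  (Absolute magnitudes on
the 12-element toy are far above the 2–3 BW of instrumented-implant gait;
see the methods vignette for why, and for what the toy does and does not
demonstrate.)

The diagnostic half of the package shows up when geometry is broken on
purpose — removing the femoral-condyle wrap cylinders from the biarticular
knee flexors:

```r
broken <- perturb_model(model, list(type = "remove-wrap",
                                    pattern = "hamstring"))
res_bad <- run_pipeline(broken, trial)
res_bad$flags$hamstrings_r$criterion_b[[3]]
#> $dof
#> [1] "hip_r_ry"
#> $start_pct
#> [1] 78
#> $end_pct
#> [1] 97
#> $phase
#> [1] "swing"
```

With the wrap gone the knee flexors' knee lever arm collapses below 5 mm at
full extension, swing-phase recruitment drives them enormously, their
hip-extension moment contribution exceeds the overall net extension moment
(the criterion-(b) flag above), and the swing-phase HCF rises by more than
1 BW relative to the intact model.

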