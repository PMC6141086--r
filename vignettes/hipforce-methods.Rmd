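---
title: "Predicting hip contact forces from gait: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hip contact forces from gait: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipforce)
```

## The problem

The force transmitted across the hip articulation during walking — the hip
contact force (HCF) — cannot be measured non-invasively; it is known in vivo
only from a handful of patients carrying instrumented implants.
Musculoskeletal models estimate it instead: motion-capture markers and
force-plate records drive a rigid-body model of the lower limb, inverse
dynamics yields the net joint moments, a muscle-recruitment optimization
distributes those moments over redundant muscle paths, and the articular
contact force follows from the limb's force balance.  The estimate is only
as good as the muscle geometry: an element whose path misses its wrapping
surface or attaches with the wrong lever arm can silently inflate the
predicted contact force by large fractions of body weight.

`hipforce` implements this pipeline end to end and, around it, the
diagnostic machinery that makes bad muscle geometry visible: a per-muscle
decomposition of the HCF, heuristic flags for anatomically suspect elements,
moment-arm sweeps with discontinuity detection, and validation metrics for
comparison against measured contact forces.

## The model

A `skeletal_model` is a tree of rigid segments connected by ball (3-dof,
intrinsic XYZ Euler) and hinge (1-dof) joints, rooted at a floating-base
pelvis with six additional coordinates.  A patella can be slaved to the knee
flexion angle through a tabulated pose coupler without adding coordinates.
Muscles are constant-strength actuators: ordered chains of attachment points
in segment frames, optionally wrapping a cylinder between two consecutive
points, with an isometric strength $N_i$ independent of length and velocity.
All quantities are SI internally; contact forces are normalized to body
weight (BW) only at reporting boundaries.

### Muscle wrapping

Each wrap is a single cylinder fixed to one segment, with an explicit
`side` convention selecting the bending sense (automatic side inference is
ambiguous at grazing incidence, so it is never guessed).  When the straight
span penetrates the cylinder, the path becomes the C¹
tangent–geodesic–tangent curve; on the unrolled cylinder the whole path is a
straight line, giving the length in closed form,

$$L = \sqrt{(l_1 + r\,\Delta\varphi + l_2)^2 + \Delta z^2},$$

with $l_1, l_2$ the projected tangent lengths and $\Delta\varphi$ the wrap
angle on the chosen side.  Length is continuous through engagement and
disengagement when the chord grazes on the wrap side; a chord forced around
the far side snaps — exactly the discontinuity the moment-arm sweep
(`moment_arm_sweep()`) is designed to detect.

### Moment arms

Moment arms use the tendon-excursion definition $r = -\partial L/\partial q$
(Richardson-extrapolated central differences, base step $10^{-5}$ rad), so a
positive arm always means positive generalized force from muscle tension.
For straight joint-crossing path pieces this equals the geometric lever
$(\mathbf{p} - \mathbf{c}) \times \hat{\mathbf{u}}$ projected on the dof
axis; the test suite holds the two routes to within $10^{-5}$ m of each
other across random postures.

## From markers to contact forces

1. **Filtering.** Markers and ground reaction forces pass through a
   second-order zero-phase low-pass Butterworth filter, cutoff 5 Hz.  The
   forward–backward application doubles the attenuation (gain 0.5 at the
   cutoff) and cancels phase.  Edges are handled by removing the
   endpoint-connecting trend and odd-reflection padding, so constants pass
   through unchanged.
2. **Calibration.** `optimize_marker_params()` minimizes the cumulative
   weighted squared distance between measured and model markers over the
   trial, jointly over per-segment length scales, permitted local marker
   coordinates, and per-frame postures (nested inverse kinematics; outer
   Gauss–Newton on the stacked residuals).  Bony-landmark markers carry
   weight 10 against 1 for cluster markers (configurable; only the ordering
   is principled).  The hip joint centre can be pinned to the Harrington
   pelvis regression, recomputed from the current ASIS/PSIS placements at
   every outer step; pelvis width is the inter-ASIS distance and depth the
   ASIS-midpoint-to-PSIS-midpoint distance.
3. **Inverse kinematics.** Per-frame weighted least squares
   (Levenberg–Marquardt, finite-difference Jacobians), warm-started from the
   previous frame.  Velocities and accelerations come from central
   differences of the filtered coordinate series (one-sided at endpoints).
4. **Inverse dynamics.** A recursive Newton–Euler pass from the feet to the
   pelvis yields each joint's net intersegmental force and moment; plate
   wrenches attach to a foot at the centre of pressure whenever the vertical
   force exceeds 20 N.  Net moments are mapped to generalized torques by
   virtual work.  The floating-base residual wrench (the upper body is a
   boundary load on the pelvis, not modelled) is reported, never hidden.
5. **Recruitment.** Per frame, muscle forces minimize the sum of cubed
   activations $\sum_i (f_i/N_i)^3$ subject to moment equilibrium
   $R f = \tau$ on the constrained dofs and $f \ge 0$.  The KKT conditions
   give the primal in closed form from the dof multipliers,
   $f_i = N_i^{3/2}\sqrt{\max(s_i,0)/3}$ with $s = R^{\mathsf T}\lambda$;
   the multipliers solve a monotone system by damped Newton with line
   search, finished when necessary by an augmented-Lagrangian solve on the
   primal activations (the cubic criterion has unbounded dual slope at
   activation onset, which can stall Newton on the active-set boundary).
   Activations are unbounded above by default, consistent with
   constant-strength actuators; an optional cap is available.  Infeasible
   frames raise an error naming the violated dofs — they are never clipped.
6. **Contact force.** On the free body of the limb distal to the hip,

   $$\mathrm{HCF} + F_\mathrm{inertial} + F_\mathrm{gravity} +
     \mathrm{GRF} + \sum_{i=1}^{M} F_i = 0,$$

   where $F_i = f_i\,\hat{\mathbf{u}}_i$ is the force of hip-crossing
   element $i$ along its line of action — the straight path piece crossing
   the joint, oriented from the distal-side point to the proximal-side
   point.  The HCF is reported in a femur-based frame (origin at the hip
   centre, proximo-distal axis along the mechanical femur axis,
   antero-posterior and medio-lateral axes completing the triad; the axis
   construction is a config block of the model), in body weights.

The same balance evaluated through an independent route — the Newton–Euler
hip intersegmental force minus the summed muscle pulls — agrees with the
free-body construction to machine precision on every pipeline frame; this
two-path identity and the per-element summation identity
$\sum_i F_i = MF_\mathrm{hip}$ are the pipeline's built-in self-checks and
are recorded in the run manifest.

## Flagging suspect geometry

Two heuristics mark actuator groups whose bookkeeping is disproportionate:

* **(a)** high contact-force contribution with low moment contribution —
  defaults: peak group $|F|$ at least 15% of the peak total HCF while the
  group's moment share stays below 5% on every constrained dof;
* **(b)** a joint-moment contribution exceeding the overall net joint
  moment with the same sign over a contiguous episode of at least 5% of the
  gait cycle.

Both thresholds are configuration with documented defaults ("high" and
"relatively low" are not quantified in the literature the heuristics come
from); flagging is monotone in them, so loosening never removes a flag.
Flags are a prompt to inspect geometry, not a verdict: in a reduced muscle
set, legitimate co-contraction (a biarticular muscle recruited for one
joint, cancelled by an antagonist at another) also produces modest
criterion-(b) episodes, particularly on the low-torque frontal and axial
dofs.  What distinguishes a genuine defect is the size and persistence of
the exceedance: in the shipped defect study, removing the femoral-condyle
wraps from the biarticular knee flexors collapses their knee lever arm from
about 4 cm to under 5 mm at full extension, recruitment must then drive them
enormously during swing, their hip-extension contribution exceeds the net
extension moment by far more than in the intact model, and the swing-phase
HCF rises by over 1 BW — restoring the wrap reverses all of it.

## The synthetic gait generator

No public motion-capture trial ships with the package; `generate_gait_trial()`
builds one cycle with known ground truth instead:

* joint-angle profiles from a truncated Fourier basis (at most 3 harmonics,
  closed-form derivatives), shaped like adult gait: ~20° hip flexion at heel
  strike extending to ~13° extension, knee flexion peaking ~40° in swing,
  small frontal/axial excursions, plus linear forward progression of the
  pelvis at 1.25 m/s;
* markers by forward kinematics, with optional i.i.d. Gaussian noise
  (σ = 0 by default; 2 mm in the robustness checks);
* a double-bump vertical GRF (sin π*u* + 0.4 sin 3π*u* over a 60% stance),
  scaled so the cycle-average vertical force equals body weight, with a
  heel-to-toe centre-of-pressure progression and small shear components;
* a reference HCF computed by running this package's own pipeline on the
  noise-free trial — self-consistent ground truth, defensible because every
  stage is separately checked against an independent oracle (closed forms,
  grid searches, a virtual-work dynamics formulation, surface-search
  wrapping bounds).

What the generator does *not* emulate: soft-tissue artefact beyond additive
noise, ground-contact consistency (the foot is not kinematically constrained
to the plate, so stance levers are larger than in real gait), bilateral
support (one plate carries the whole cycle-average body weight), and
physiological muscle redundancy (12 elements against 169 in a full-geometry
model).  Consequently the toy's absolute HCF magnitudes are far above the
2–3 BW of instrumented-implant gait — peaks near 25 BW — and passing tests
demonstrate the *mechanics* (identities, oracles, recovery, defect
detection), not clinical realism of magnitudes.  The toy's fixed study
conditions are: 78 kg, 1.72 m subject; 1.0 s cycle at 100 Hz (101 frames);
60% stance.

## Numerical choices

* Constrained dof set: all joint dofs of joints spanned by at least one
  muscle (hip + knee in the toy); the ankle's net moment and the pelvis
  wrench are reported as ideal residuals.
* Recruitment tolerance $10^{-9}$ (relative to the torque scale); no warm
  starts, fixed least-squares initialization, so results are independent of
  frame ordering and muscle column order.
* IK convergence $10^{-14}$ on the objective decrease; rank-deficient
  marker sets raise an underdetermined-pose error listing the evidence.
* Tendon-excursion step $10^{-5}$ rad with Richardson extrapolation.
* Wrap engagement: projected chord-to-axis distance below the radius; no
  hysteresis.  Endpoints inside the cylinder or on its axis are errors, not
  silent clamps.
* Resampling for validation metrics: monotone cubic interpolation onto a
  101-point 0–100% cycle grid; peak windows 0–30% (loading) and 30–60%
  (terminal), configurable.
* Gap filling: linear, at most 0.1 s; longer gaps leave the marker missing
  for those frames.

## Known limitations

Single-cylinder wrapping only (no ellipsoids, tori, or multi-surface
obstacle sets); one leg modelled, upper body lumped into the pelvis; no
Hill-type force–length–velocity muscle behaviour (constant-strength
actuators); no C3D reader — TRC and CSV are the supported trial formats; the
defect-study contrast is qualitative by design, asserting directions and
flag presence rather than magnitudes.
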