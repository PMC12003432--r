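---
title: "Methods: surgery-specific upper-limb models, from geometry to induced acceleration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surgery-specific upper-limb models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(reconarm)
```

This vignette is the package's own account of its modeling choices: the
model and its assumptions, the parameters that matter, what the synthetic
fixtures emulate (and do not), numerical choices, and known limitations.

## The model

`reconarm` builds a right-arm serial chain — thorax (welded to ground,
origin at the suprasternal notch; x anterior, y superior, z right), humerus,
forearm, hand — with four generalized coordinates: an intrinsic three-
rotation shoulder (elevation plane about y, elevation angle, axial rotation
about the humeral long axis) and elbow flexion. The hand is welded to the
forearm; the wrist is not a modeled degree of freedom, and there is no
independent scapula or clavicle (the analyses the package supports report
only thoracohumeral quantities). The three surgical variants share this
skeleton and the 21-muscle path set and differ only in:

* **torso mass properties** — an analytic stadium solid (rectangle with
  semicircular caps, extruded along the trunk) with a 405-cc breast region
  superposed at the variant's tissue density: native 0.95 g/mL
  (lumpectomy), silicone 1.05 g/mL (implant), DIEP flap tissue 0.84 g/mL.
  Superposition is exact: the region's excess mass, its own small-cylinder
  inertia and parallel-axis transfers are applied analytically, so a scheme
  at native density is the identity, and composing a scheme with its inverse
  recovers the base to machine precision.
* **pectoralis major routing** — the implant variant replaces the sternal
  and ribs compartments' chest-wall via points with a cylindrical wrapping
  surface beneath the compartments.

### Why a three-rotation shoulder

The validation and induced-acceleration outputs are all expressed in
thoracohumeral coordinates, so shoulder-girdle kinematics would add state
without adding reportable output. The cost is a gimbal singularity at
exactly 0° elevation (the elevation-plane and axial axes align). The static
strength tests are unaffected (no mass-matrix inverse is needed), and the
shipped rotation motion holds 8° of elevation in a 30°-anterior plane —
consistent with dynamometry practice of a towel roll under the arm — which
keeps the mass matrix well conditioned.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| implant volume | 405 | cc | most common implant size; configurable |
| implant projection | 4.4 | cm | manufacturer spec; read as cylinder length, radius from V = pi r^2 L (≈5.41 cm). The alternative reading (projection = radius) is `projection_is = "standoff"` |
| tissue densities | 0.95 / 1.05 / 0.84 | g/mL | native breast / silicone / DIEP flap |
| breast region | 405 cc cylinder, r = 4.5 cm, centred (0, -0.10, +0.09) m | — | unilateral, anterior chest; +z side reproduces the published sign pattern of COM and products of inertia |
| torso stadium | depth 23.8, breadth 27.6, length 52 | cm | 50th-percentile adult female chest/trunk; frozen in `inst/extdata/anthropometry_f50.json` |
| segment masses/inertias | see fixture | — | adult-female segment-inertia fractions of body mass (64 kg) and length |
| dynamometer contacts | 0.265 m from elbow (rotations); 0.333 m from GH (planar) | m | fixed from the internally consistent effective levers implied by the cohort's force→moment pairs |
| Fmax female scale | 0.6 | — | global scale from young-male reference maxima; an assumption, exposed in the fixture |
| moment-arm step | 1e-5 | rad | central tendon-excursion difference; refined 100x with a warning if it straddles a wrap on/off transition |
| activation floor `a_min` | 0.02 | — | mirrors the reference tracking tool's excitation floor; set 0 for strict minimum effort |
| reserve penalty `weights` | 1e4 | (N m)^-2 | prices a reserve moment of 0.01 N m like a full activation; keeps reserves ~1e-3 N m on shipped motions |
| PD gains kp, kv | 400, 40 | s^-2, s^-1 | critically-damped 20 rad/s error dynamics at the 10 ms step |
| motion durations | 4 s phases, 1 s pause | s | not stated by the source protocols; chosen once as slow, quasi-static functional speeds |

## Muscle paths and wrapping

Moment arms come from tendon excursion, r = -dL/dq, with path lengths summed
over straight segments; the wrapped segment is replaced by a
tangent–geodesic–tangent route solved in the plane normal to the cylinder
axis, with axial travel distributed along the planar arc length (helical
geodesic). The wrap side is a direction in the cylinder frame (anterior for
the implant), and endpoints strictly inside the cylinder raise a geometry
error naming the point. The cylinder is treated as infinite along its axis
for contact decisions; `half_length` is carried for serialization and
reporting only.

Attachment coordinates are a calibrated fixture, frozen in
`R/build_model.R` and audited by `scripts/calibrate_fixture.R`: compartment
moment arms were placed in published anatomical envelopes (pectoralis major
an adductor of 1–6 cm across 0–120° elevation; cuff rotation arms 1–2.5 cm;
deltoid compartments elevators with small rotation side-arms). Two modeling
devices deserve note:

* anterior/middle deltoid and supraspinatus use a **thorax-fixed via point**
  at the edge of the humeral head. The head is nearly spherical about the
  fixed glenohumeral centre, so its surface contact point is
  quasi-stationary in the thorax frame; this reproduces the bell-shaped
  deltoid elevation arm (peak ≈ 4 cm near 60°) without wrap objects, which
  are reserved for pectoralis major by design.
* the pectoralis insertions sit 2 cm anterior of the humeral shaft axis,
  giving internal-rotation arms of 1–1.6 cm.

With this geometry the implant variant's summed pectoralis moment-arm
magnitude is strictly below the lumpectomy/flap value at every elevation
angle sampled in 0–120° (margin ≥ 1.7 cm of summed arm at the tightest
angle), and lumpectomy and flap are identical to 1e-12 m because their
paths are byte-identical.

## Static validation

For each of five strength-test postures the cohort-mean dynamometer force is
applied at the documented contact point, opposing the tested motion, and
`static_joint_moments()` returns tau = -(sum J'F + G). The primary
coordinate is axial rotation for external/internal rotation, elevation plane
for horizontal ab/adduction, and elevation angle for elevation. Contact
geometry is shared across groups, so rotational predictions scale exactly
with the applied force (gravity is parallel to the vertical rotation axis
there). The published lumpectomy-elevation and horizontal-adduction cells
imply effective levers inconsistent with the other groups under shared
geometry; this package keeps one shared geometry, which lands those cells
within 1 SD of the measured means rather than reproducing the published
predictions for them — the validation claim asserted by the tests is the
within-2-SD envelope for all 15 cells.

## Activation solving and induced acceleration

The tracking stage replaces full computed muscle control with per-step
static optimization under PD tracking: the model is integrated forward
(semi-implicit Euler, 10 ms); at each step the desired acceleration is the
trajectory feedforward plus PD feedback; the muscle redundancy problem

  min  sum(a^2) + w * sum(reserve^2)   s.t.  B a + reserve = tau_required,
  a_min <= a <= 1

is solved exactly by an active-set method on the equivalent box-constrained
ridge problem (the constraint is eliminated; columns of B are moment arms
times rigid-tendon unit tensions with a Gaussian force–length curve
anchored at optimal fiber length in the neutral posture). Because the
realized acceleration equals the commanded one, re-integrating open loop
with the stored controls reproduces the realized trajectory exactly, and
the realized trajectory tracks the input to well under 0.5° RMS.

Induced acceleration applies one source's generalized force at a time
through q̈ = M⁻¹ tau and maps to the hand with the point Jacobian; gravity,
velocity (Coriolis/centrifugal plus the J̇q̇ term) and the penalized
reserves are carried as three additional named sources so superposition
closes identically (residual < 1e-8 m/s² is asserted at every step of all
three motions). The mass matrix is assembled from body Jacobians
(M = sum m Jv'Jv + Jw' I Jw), solved by factorization, and checked against
an independent kinetic-energy finite-difference oracle. Contributors are
ranked by time-integrated absolute contribution along an axis (peak
magnitude is available via `metric = "peak"`), ties broken by name.

## What the fixtures emulate — and what a green test does not establish

The anthropometry, muscle geometry, and strength tables are synthetic
fixtures built from population constants and the published cohort summary
statistics; they emulate a 50th-percentile adult female and group-mean
loads, not any individual patient. Green validation tests establish that
the engine's statics are correct and that one reasonable fixture reproduces
the published strength envelope; they do not establish subject-specific
accuracy, scapulothoracic effects, or treatment effects beyond the modeled
density and path changes.

The qualitative induced-acceleration rankings are the one place the package
knowingly diverges from the published result, and the acceptance test for
them is left failing rather than tuned: with 21 muscles, 4 DoF and a
minimum-effort recruitment, elbow-flexor gravity demand keeps brachialis
and biceps long head active throughout the rotation task, and their
inertial coupling to anterior–posterior hand acceleration outranks the
near-floor triceps long head and biceps short head that the reference
pipeline (50 muscle paths, computed muscle control with excitation floors
and activation dynamics) reports. Matching those sets exactly would require
tuning the fixture against the acceptance criterion itself. The package's
rankings still reproduce the robust qualitative findings: large-volume
shoulder muscles (infraspinatus, subscapularis, deltoid) dominate, elbow
muscles dominate the superior–inferior axis, and the pectoralis major
compartments carry large contributions in elevation and horizontal tasks.

## Numerical choices

* moment arms: central difference, 1e-5 rad; wrap-transition refinement.
* velocity bias forces: Christoffel assembly from central differences of
  the mass matrix (h = 1e-6 rad); exact for the quadratic kinetic energy up
  to O(h²).
* J̇q̇: directional central difference of the hand Jacobian along q̇.
* QP: strictly convex; active-set iterations bounded at 200 with exact
  KKT release checks; fully deterministic, no random number use anywhere in
  the shipped pipeline (the CLI seed flag is reserved).
* serialization: JSON at full floating precision, fixed field order;
  write → read → write is byte-identical.

## Known limitations

* No scapulothoracic articulation: trapezius/serratus anterior are absent,
  which the source analyses also acknowledge for horizontal tasks.
* Wrapping is single-cylinder and pectoralis-only; deltoid head wrap is
  approximated by thorax-fixed vias.
* Rigid tendon and a global 0.6 female force scale; no activation dynamics.
* The implant cylinder is infinite for contact decisions; extreme
  out-of-range postures can place the humeral insertion inside it, which is
  reported as an error rather than resolved.
* One implant size (405 cc) is the default; other sizes are parameters, not
  validated configurations.
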