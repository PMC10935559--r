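---
title: "Methods of the patellofemoral digital twin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods of the patellofemoral digital twin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the numerical choices, and the design
decisions behind `pftwin`: what is simulated, which knobs matter, what the
synthetic bench does and does not emulate, and where the known limitations
lie. It states no empirical result that the test suite or
`scripts/acceptance.R` do not themselves compute.

## 1. The mechanical model

The system has three rigid bodies. Femur and tibia are *guided*: their
poses are prescribed from (synthetic) marker data and they contribute no
unknowns. The patella is free with six degrees of freedom. The world frame
is the femur frame at rest: `x` sagittal (positive proximal, along the
trochlear groove), `y` medial–lateral (medial positive), `z` height off the
groove floor; gravity acts along `-z` (the bench lies anterior-side up).

Two linear spring–dampers act as tendons. The tension convention is
`F = K (L - L0) + c L̇` with default `c = 0.01 K`. The damping sign is
implemented *dissipatively*: the damper resists length change in the
tension convention, so its work over any closed length cycle is
non-positive. The variant with a minus sign on the damping term, which
would inject energy over a cycle, is available behind
`damping_sign = "printed"` for comparison but is not the default — a
damper that feeds energy contradicts its purpose. An optional rigid series
element (`rigid_extension`, default 0; 1.96 cm in the lengthened
configuration) shifts the zero-tension length.

Normal contact uses the Flores dissipative model
`F = k_n δ^p [1 + 8(1-ε)/(5ε) δ̇/δ̇₀]` along the contact normal, with no
tangential (friction) force — the physical articulation is lubricated.
Conventions and guards:

* `p = 1.5` (the classical Hertz exponent; a configurable parameter).
* `k_n` is a scenario parameter. The bench default is `3e6 N/m^1.5`,
  roughly the Hertz sphere-on-plane stiffness `4/3 E* sqrt(R)` for an
  effective contact modulus of a few tens of MPa: stiff enough that the
  static indentation stays below ~5 % of the button radius at peak load,
  compliant enough to integrate cleanly at the 1 ms step
  (`hertz_stiffness()` computes the Hertzian value for other moduli).
* `δ̇₀` is latched at the first accepted step of each contact episode and
  held until separation. If an episode opens with no meaningful approach
  speed (`δ̇₀ ≤ 1e-4 m/s`, e.g. initialization inside contact or a grazing
  episode) the dissipative term is disabled for that episode.
* The compression ratio `δ̇/δ̇₀` is clamped at 1, its value at the start of
  a clean impact. Without the clamp, chattering micro-episodes that latch a
  tiny `δ̇₀` can amplify the bracket without bound and destabilize the
  integration; the clamp is inactive in a clean compression–restitution
  cycle.
* The force is clamped non-tensile (`F ≥ 0`).
* A sphere center *below* the surface is honored as deep penetration
  (`δ = r + |d|`, capped at `2r`) only as the continuation of an existing
  episode or a sub-radius overshoot. A body arriving from underneath the
  height field is not a new contact — without this rule, a dislocated
  patella falling past the lateral flank would re-enter the surface from
  below and receive an enormous spurious force.

The bounce experiment (test suite and acceptance script) drops a button on
a plane without gravity and compares rebound to impact speed: the model is
constructed to approximate the coefficient of restitution, and does so
within a few percent at ε = 0.7 (gravity's impulse over the finite contact
time would otherwise bias the ratio, which is why the experiment is
gravity-free).

## 2. Integration: augmented-Lagrangian index-3 with projections

Unknowns per step are the free-body accelerations (world-frame linear,
body-frame angular). Newmark with γ = 1/2, β = 1/4 (average acceleration,
unconditionally stable, no numerical damping) discretizes translations
directly; orientations advance through the quaternion exponential of the
Newmark rotation increment, so unit norm holds by construction and no
separate normalization constraint is needed. Position-level constraints
(spherical joints, distance constraints) enter through an augmented
Lagrangian: the penalty is `alpha` times the leading mass (default
`alpha = 1e7`), with multiplier updates until `‖Φ‖∞ ≤ pos_tol`
(default 1e-8 m). After acceptance, velocities and accelerations are
projected mass-orthogonally onto the constraint subspace
(`‖Φ_q q̇‖∞ ≤ vel_tol`). The inner Newton solve uses a cached
finite-difference Jacobian (refreshed every 25 steps or on slow
convergence) with a monotone backtracking line search; a step whose Newton
solve fails is retried at half the step size (down to h/16). Faceted mesh
contact makes the force field only piecewise smooth, so for mesh backends
the solver accepts residuals below the facet force granularity
(0.05 N per kg of leading mass) instead of the smooth-case tolerance.

Verified behaviors (all computed in the tests): free fall is exact
(constant acceleration), the small-angle pendulum period is within 0.5 % of
`2π√(L/g)` and its error falls fourfold when the step is halved
(second order), energy drifts by less than 0.1 % over 2 s for a
conservative contact oscillator, and constraint residuals stay below the
tolerances at every accepted step.

Default steps: 1 ms for the analytic and fine-mesh backends; 0.1 ms for the
coarse mesh, whose facet-induced force jumps otherwise excite the Newton
solve (an 0.05 ms option exists for the most demanding runs).

For the standard bench topology (one free patella, two guided anchors, one
analytic contact) a compiled stepper (`src/bench_sim.cpp`) mirrors the
generic R stepper; agreement between the two paths is covered by a test
(equality to ~1e-9 m over a shared window). The compiled path is what makes
genetic-algorithm calibration affordable (≈ 0.3 s per candidate
simulation).

### Static equilibrium

Initialization is local-first: a short, strongly damped dynamic settle
from the recorded patella pose (frozen guidance, added linear and
rotational viscous damping) finds the stable equilibrium of that pose's
basin — the bench also owns a lower-energy *dangling* equilibrium far from
the groove that a global energy minimization would reach instead. A
step-capped damped Newton then polishes the generalized-force residual to
`force_tol` (1e-6 N) without leaving the basin; several exact force zeros
can coexist along the nearly flat rotational valleys, which is also why
the uncapped Levenberg–Marquardt solve (`minpack.lm::nls.lm`) is reserved
for the fallback path. The result is checked for dynamic stability through
the symmetrized force Jacobian; a negative-curvature (saddle) direction
triggers a settle-based escape and re-polish. Mesh backends equilibrate on
the exact order-5 analytic surface (identical geometry): their faceted
force field is only piecewise smooth, which defeats any Newton polish
below the facet force granularity. A converged state restarts with
< 1e-4 m drift over 1 s of frozen guidance (tested).

## 3. The synthetic bench

The physical test rig that motivates this package (3D-printed bones with
commercial implants, optical markers, spring tendons, load cells) is not
publicly deposited, so the package generates a synthetic equivalent whose
ground truth is known exactly.

**Trochlear surface.** A bivariate polynomial height field of total order
5 (see `?groove_params`): a sagittal parabolic sweep (radius 45 mm), a
quartic cross-section with ridges at ±19 mm and depth scale 15 mm, a cubic
asymmetry making the lateral ridge 10 % higher than the medial one, and a
linear depth taper from full depth at the distal end to 32 % of it at the
proximal entrance. The modeled flange ends just past the ridge crests
(transverse span 1.10 halfwidths), as an implant edge does — a patella that
crosses the lateral ridge leaves the articulating surface. The choices
encode the anatomy that matters for instability: a groove that is deep
where the patella sits in flexion and shallow at the proximal entrance it
reaches near full extension, with transverse curvature everywhere milder
than the button (10 mm radius), so contact stays single-point. Because the
truth is polynomial of order 5,
the order-5 surface fit reproduces it with R² = 1 — the analytic backend's
geometry error can be made exactly zero, which is what makes the
backend-agreement comparison meaningful. Meshes are generated at the
coarse (0.1 mm / 1°) and fine (0.006 mm / 0.5°) quality targets by lattice
refinement; every vertex lies exactly on the analytic form.

**Attachments and phenomenology.** The quadriceps anchor sits proximally
(19 cm above the knee center, medial or lateral by ±2 cm); the tibial
tubercle sits 6.8 cm distal on the tibia, *medial* +1.0 cm or *lateral*
−4.6 cm. The asymmetry is deliberate: a medial attachment lies inside the
groove track, so its lateral pull is self-limiting (it vanishes as the
patella approaches the attachment line), while the lateral attachment lies
beyond the lateral ridge and keeps pulling as the patella climbs. As the
knee extends, the tubercle rises toward the patella: the tendon becomes
more horizontal, pressing less and pulling more laterally, exactly when
the patella has slid into the shallow proximal entrance. The
femur-medial/tibia-lateral configuration therefore tracks normally through
flexion and dislocates laterally during extension (at ≈ 26° knee flexion
under the default motion), while medializing the tibial attachment — the
bench analogue of tibial tuberosity transfer — removes the dislocation
with everything else unchanged, under both collision backends. These
layout constants were chosen once to reproduce that clinical phenomenology
and are documented fixtures, not fitted quantities.

**Tendon straps.** Each tendon is modeled as a two-strand strap: two
parallel spring-dampers of half stiffness, offset ±8 mm medially and
laterally at both ends; the strand tensions sum to the load-cell channel
and the classical single-spring law. The strap width is what gives the
patella its roll stiffness about the long axis — with point attachments,
patellar roll is nearly indeterminate (the roll energy landscape is almost
flat over tens of degrees) and the static equilibrium is a saddle whose
unstable mode contaminates tilt readouts.

**Motion and markers.** The tibia follows
`θ(t) = 45° + 40° sin(2πt/2 s)` (two cycles, starting near 45° flexion,
spanning ≈ 5°–85°); the femur rocks ±1.5° about the hip. Four-marker
clusters on femur, tibia and a patellar post are sampled at 100 Hz with
optional iid Gaussian noise; the guided-body inputs are the 8 femur+tibia
markers, the patellar cluster serves validation. Marker processing:
zero-phase second-order Butterworth at 12 Hz (phase-true trajectories are
required for rheonomic guidance), SSA with window 30 keeping components to
99 % of trajectory-matrix variance, and pose reconstruction from three
non-collinear entities per body. Guidance between the 100 Hz samples is
cubic-spline interpolated (positions and quaternion components,
renormalized), with angular velocity from the quaternion derivative.

**What the bench does not emulate.** Real implant geometry (the synthetic
groove is idealized and left–right symmetric up to the ridge-gain term),
marker occlusion and soft-tissue artifact, load-cell noise, friction, and
tibiofemoral contact. Passing tests on this bench therefore demonstrate
the correctness and internal consistency of the machinery — detection,
dynamics, calibration, prediction — not clinical validity on any specific
implant.

**Post-dislocation states.** A dislocated patella leaves the modeled
implant surface; its subsequent free flight on two point-attached springs
is outside the model's scope (the physical trial also ends at
dislocation). The trajectory is therefore frozen 50 ms after a sustained
loss of contact; events are classified from how the separation begins.
A small viscous rotational damping on the patella (2e-4 N·m·s) stands in
for the distributed resistance of tendon straps that point attachments
cannot transmit; without it the free patella can spin up unphysically
after separation.

## 4. Collision backends

**Mesh-to-mesh.** AABB trees are built once per mesh in its body frame
(median split of the dominant axis, one triangle per leaf); at query time
the opposing mesh is posed into the tree frame. Narrow phase: the chord of
each candidate triangle on the other triangle's plane is clipped to that
triangle, giving intersection segments that are chained into contours by
endpoint hashing (1e-9 m quantum). Per contour: contact point =
length-weighted contour centroid; normal = area-weighted mean of the
penetrated reference-surface face normals, oriented toward the opposing
body; indentation = deepest opposing-body vertex below the reference
surface along the patch normal (ray casting through the tree). Open
contours fall back to deepest-point contact with a warning; near-coplanar
pairs are retried under a deterministic 1e-9 m normal jitter. Multiple
simultaneous contours each form their own patch and episode; their forces
sum.

**Analytic.** The closest point on the fitted polynomial surface to the
sphere center solves the two-variable stationarity system by damped
Newton, seeded from the vertical projection plus a ring of 8 starts (the
groove ridges can host multiple local minima); in the simulation loop the
previous footprint warm-starts the solve and the multi-start only runs
when the warm seed fails to converge to an interior stationary point.
Contact exists iff the center-to-surface distance is below the sphere
radius. Outside the fit domain the surface is not extended: a sphere
leaving the domain ends the episode and the exit is logged as a candidate
dislocation marker. All polynomial orders share one fit domain and frame.

Backend comparison is replay-based: contact forces are re-evaluated along
one recorded bench trajectory with each backend, so differences isolate
contact geometry rather than compounded dynamics. The fine mesh agrees
with the exact order-5 analytic surface to about 1 % of peak force, the
coarse mesh to about 5 %, and the coarse mesh carries roughly twice the
spectral power above 50 Hz — the discretization-induced artificial force
oscillation that motivates the analytic backend.

## 5. Validation metrics and event detection

Patellar kinematics are reported in the femoral body frame (avoiding
world-frame error accumulation): sphere-center coordinates plus a fixed
Y–X–Z Euler decomposition of the relative orientation — flexion about the
medial-lateral Y axis, tilt about the patellar long X axis, rotation about
the anterior-posterior Z axis. The naming follows the axes, not any
particular table labeling. `rmse_report()` computes channel-wise RMSEs
(contact force; tibial and femoral spring tensions; the three angles; the
three coordinates in mm; mean distance error; runtime ratio) after
resampling onto the reference time base; it is symmetric in its arguments.

`detect_events()` classifies sustained contact-loss episodes (> 50 ms) from
how they begin (first 150 ms): *dislocation* if the sphere center has
crossed the lateral ridge line while knee extension continues;
*high-riding* if the center stays proximal to the groove entrance with no
engagement while flexing above 25°. The thresholds (persistence, ridge
line at one groove halfwidth, entrance at 0.55 of the sagittal
half-extent, 25° flexion) are fixture-calibrated constants reported with
every result.

## 6. Tendon-parameter identification

`calibrate_tendons()` estimates (K₁, L₁, K₂, L₂) inside a ±30 % box around
the scenario defaults by minimizing the RMS distance error (mm) of the
simulated sphere center against the observed kinematics in the femur
frame; forces are deliberately not part of the objective (motion is what
computer-assisted surgery systems record). Every candidate simulation
starts from the *observed* initial state rather than its own equilibrium:
the observed start is the true parameters' equilibrium, which makes the
objective exactly zero at the truth and adds an initial-transient penalty
that sharpens the otherwise shallow stiffness directions. No GA library
exists in the target environment, so the optimizer is a compact in-package
real-coded GA (tournament selection, BLX-style blend crossover, Gaussian
mutation, elitism, box clamping, fixed seed) with population 24 over 20
generations — smaller than a desk-scale MATLAB `ga` run, chosen so a full
calibration stays near three minutes — followed by a box-clamped
Nelder–Mead polish of the winner. On noiseless synthetic motion of the
pathological configuration this recovers all four parameters within a few
percent (the acceptance script prints the per-parameter errors).

Treatment prediction re-simulates the calibrated model under an edit
(default: tibial attachment medialization). An empty edit reproduces the
calibrated pathological run bitwise — the whole pipeline is deterministic
under fixed seeds.

## 7. Problem sizes

The shipped study conditions are: two 2 s flexion–extension cycles at
100 Hz marker sampling, 1 ms integration (4000 steps per full run),
calibration against the first 1.0 s of the pathological motion,
GA budget 24×20 evaluations plus polish, fine-mesh classification runs
over the first 2.2 s (covering the first full extension and the
dislocation), and oracle checks at 100 random AABB probes / 50 random
closest-point queries. These sizes are the package's chosen desk-scale
conditions; all headline quantities are recomputed at these sizes by
`scripts/acceptance.R`.

## 8. Known limitations

* No friction, no tibiofemoral contact, no muscle forces: passive guided
  motion only.
* Linear point-to-point tendons; real tendons are wide, wrapping and
  nonlinear. The rotational damping stand-in (Section 3) is the visible
  consequence.
* The mesh backend reports a single averaged patch per contour; conforming
  (area) contact is reduced to one force line per contour.
* Post-dislocation dynamics are intentionally not modeled (frozen state).
* The synthetic R² values of the low-order fits depend on this synthetic
  groove; they order the backends qualitatively but are not comparable to
  any specific implant's values.
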