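---
title: "Methods: a desk-scale kinetic vs kinetic-kinematic knee model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale kinetic vs kinetic-kinematic knee model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(kneedrive)
```

## Purpose

Musculoskeletal workflows feed finite-element knee models in two broad ways:
*kinetically*, by applying the joint contact forces and moments estimated from
gait analysis and letting the joint find its own secondary kinematics, or
*kinetic-kinematically*, by additionally prescribing some measured rotations.
The choice changes the computed cartilage response, and the difference is a
modelling decision, not noise. `kneedrive` provides a small, fully synthetic,
fully reproducible laboratory for studying exactly that choice: the same
joint, the same stance-phase loading, driven four different ways.

The package is not a clinical tool. Every input is generated; the value is in
the *contrast between driving modes* under controlled conditions, with
residuals, complementarity, and analytic oracles checked at every step.

## The mechanical model

All quantities use N, mm, MPa and s. The tibia is fixed; the femur is a rigid
body with 6 degrees of freedom `q = (tx, ty, tz, vv, ie, fe)` (translations in
mm; varus-valgus, internal-external, flexion-extension rotations in rad,
applied in a fixed Cardan order, flexion last so that flexion is always about
the femoral fixed axis). The axes are x anterior, y proximal, z lateral
(right knee).

### Cartilage: poroelastic contact columns

The tibial plateau is tessellated into vertical columns on a regular grid
(default spacing 1 mm, about 1550 columns; tests use 2 mm, about 380
columns). Each column is an independent 1-D transversely isotropic poroelastic
pillar of local thickness `h0` — an elastic-foundation discretization. Depth
is resolved with `depth_layers` sub-layers (default 3 for the joint run; the
oracle tests use up to 32) and time is integrated with backward Euler. This is
the standard Terzaghi consolidation problem per column: uniaxial strain, axial
Darcy flow, drained at the articular surface, impermeable at the bone.

Two closed-form oracles pin the implementation down:

* the **isotropy limit** of the transversely isotropic elasticity matrix must
  reproduce the Lamé form to machine precision (`tipe_elasticity_matrix()`),
  and the default cartilage matrix must be positive definite;
* a column held at a **constant step load** must follow Terzaghi's series
  solution for the pore-pressure profile (`terzaghi_pressure()`). At 32
  layers and `dt = t_char/500` the relative RMS error is about 0.3 %
  (acceptance threshold 2 %). Note the boundary condition: the series
  solution is for a *held traction*, so the check drives the column in load
  control. Comparing a *held displacement* (relaxation) transient against the
  step-load series is a wrong pairing and fails spectacularly — an early
  version of our own test did exactly that.

One deliberate limitation: with `n` layers the *instantaneous* (undrained)
stiffness of the backward-Euler column is finite (order `2n·M_t/h` per unit
area) rather than infinite as in the continuum undrained limit. The joint
march uses `dt = 6 ms` per step where this matters little; the oracle tests
use fine layering where it matters more.

For the joint solve, each column's backward-Euler update is condensed into an
affine law for the surface traction, `T(w) = alpha + beta·w`, where `w` is the
imposed overlap and `alpha` encodes the column's consolidation history. The
affine coefficients for all columns are precomputed once per time step
(`column_bank`), so each Newton iteration costs a vector operation.
Contact is unilateral: `T = max(0, ·)` with the complementarity product
`T·gap` reported at every step (typically 0 to 1e-10).

### Menisci: elastic spacer in series

Columns under the meniscal annulus (outer 40 % of the plateau dish) carry the
condyle load through a meniscus wedge in series with the cartilage. The wedge
is transversely isotropic elastic (no flow) and is anchored by two horn
springs (350 N/mm each) acting over the annulus; both combine into a series
stiffness `k_series`, giving a softened effective foundation
`T = gamma·(alpha + beta·w)` with `gamma = 1/(1 + beta/k_series)` and a
cartilage share of the overlap `w_cart = w − T/k_series`. This reproduces the
load-sharing role of the meniscus without modelling hoop stress explicitly.

### Ligaments and the extensor mechanism

ACL, PCL, MCL and LCL are tension-only bilinear springs (quadratic toe region
up to 6 % strain, linear beyond) with literature stiffnesses (380, 200, 100,
100 N/mm) and prestrains (5 % cruciates, 4 % collaterals). Reference lengths
are frozen at the reference pose.

Geometry variant A adds a point patella: a 3-DOF node loaded by the
quadriceps force, restrained by the patellar tendon (545 N/mm spring to the
tibial tuberosity), two patellofemoral trusses (MPFL/LPFL), and a smooth
trochlear contact sphere. Its equilibrium is solved exactly at every femur
configuration (residual below 1e-8 N; the system is conservative, so a BFGS
energy minimization globalizes the Newton polish across the tension-only
kinks). The net force the mechanism transmits to the femur satisfies the
identity `F_femur = QF + T_pt·(tuberosity − p)/L` — muscle pull plus tendon
reaction — which is asserted in the tests.

Two modelling choices here deserve a note:

* **Free quadriceps node.** The quadriceps force is nominally applied at a
  reference point `RP_Quad` connected to the patella by the quadriceps-tendon
  spring. A free node in static equilibrium transmits exactly the applied
  force along the line of action, whatever the spring constant: if the node
  carries external force `F` and one spring, equilibrium forces the spring
  tension to equal `|F|` along `F`. So the implementation applies the
  quadriceps vector directly at the patella along the flexion-dependent line
  toward the posed `RP_Quad`; the QT stiffness and prestrain remain in the
  configuration but are documented as not entering the force balance.
* **Regularization spring.** When the quadriceps force is zero and every
  patellar element is slack, the patellar Jacobian is singular. A weak spring
  (0.1 N/mm) to the femur-posed reference point removes the singularity and
  contributes at most a few tenths of a newton under load.

### Tibial geometry

The plateau has two shallow dishes (different medial/lateral radii) and a
posterior slope (default 7°, an anatomical value chosen a priori). The slope
matters scientifically: it couples anterior-posterior force to axial
compression, which is the mechanism through which the quadriceps surrogate of
mode D acts on the axial reaction (about 0.13 BW of axial reaction per BW of
posterior force at this slope and ligament set).

## Driving modes

| mode | geometry | prescribed rotations | moments applied | quadriceps |
|------|----------|----------------------|-----------------|------------|
| A | with patella | FE | 0.5·M_ie + 0.5·M_vv | full mechanism |
| B | no patella | FE, IE | none (option: 0.5·M_vv) | none |
| C | no patella | FE, IE | none | none |
| D | no patella | FE, IE | none | AP surrogate `s·QF_ap` added to `F_ap` |

All modes apply the measured force triplet (AP, DP, ML). Mode A is the
kinetic model: only flexion is prescribed, the internal-external and
varus-valgus moments are applied scaled by 0.5 (`moment_scale`, the standard
assumption that muscles absorb half the external moment), and the full
extensor mechanism loads the femur. Modes B-D prescribe IE on top; C and D
are identical except that D re-injects the anterior-posterior component of
the quadriceps force scaled by `qf_scale` (default 1).

The remaining free DOFs (translations plus VV, plus IE in mode A) are solved
by damped Newton on the rigid-body residual with a finite-difference
Jacobian, to tolerances of 1e-8 BW (force) and 1e-8 BW·mm (moment). A
singular Jacobian names the unconstrained DOF in the error.

### Protocol and path following

Each run is: settle to first contact (pure −y translation), ramp the first
gait row in `init_increments` increments, then march `n_steps` (default 100)
steps of `dt = 6 ms` across stance, committing one consolidation step per
increment of the march.

`init_increments` defaults to 40, and the value matters more than it looks.
With tension-only springs and unilateral contact the static problem has
*multiple equilibrium branches*; a coarse ramp can hop branches, after which
two runs that are algebraically equivalent diverge by millimetres. Forty
increments keeps every tested configuration on the quasi-static continuation
path (verified stable against 80 and 160 increments). This is a
path-following refinement chosen for robustness, not a tuned constant.

## The synthetic generator

`build_geometry(seed)` perturbs the canonical geometry (condyle semi-axes,
dish radii, cartilage thickness field, insertion points) with seeded jitter
of about 3 % relative and 0.5 mm absolute — the scale of segmentation
variability — and returns paired variants A (with patella) and B (without)
that share all common surfaces, so mode contrasts are never confounded by
geometry. `generate_gait(seed)` produces a 101-point stance-phase table with
the canonical double-peaked axial force (peaks ≈ 1.1 and 1.0 BW), an
early-stance quadriceps peak (≈ 2.2 BW), flexion 5-30°, IE ±4°, plus smooth
seeded noise (5 %). The defaults *are* the study conditions; they were chosen
once from physiological gait corridors and deliberately never adjusted
against test outcomes. Realism limits worth naming: a point patella has no
patellar contact map; the gait waveforms are idealized single-subject shapes,
not a population; column independence ignores in-plane shear coupling.

## Outputs and analysis

`simulate_stance()` returns a `knee_sim` with a per-step tibble (pose,
reactions in BW, contact counts, residual diagnostics) plus per-column fields
(traction, cartilage compression, mean pore pressure). `tidy()`/`glance()`
follow broom conventions; `autoplot()` draws the reaction and gait curves.
`compartment_response()` averages over *contacting cartilage columns only*
(empty contact gives `NA`, not 0) and reports peak pressure, log strain, mean
pore pressure, and the maximum principal total stress from the closed-form
uniaxial-strain stress state. `compare_models()` computes mean/max/RMS
differences over pose and reaction series plus per-column traction snapshots
at 20/50/80 % stance; `qf_scale_sweep()` minimizes the aggregate discrepancy
over a grid of `qf_scale` values.

`run_pipeline()` writes the full artifact set (gait CSV, per-mode step and
compartment CSVs, legacy-ASCII VTK contact maps, comparison metrics, and a
`manifest.json` keyed by a content hash of the configuration). The hash
excludes the output directory, so the same study written to two places is
byte-identical — and the test suite asserts that, byte for byte.

## The round trip, and one honest failure

Two results frame the scientific use of the package.

**The round trip is exact.** Run mode A, extract its solved IE trajectory,
and feed it back as the prescription of mode B with the VV moment retained
(`vv_moment_in_B = TRUE`). Mode B then solves mode A's equations minus the
IE-moment row, at the point where that row is already satisfied — so the
solutions must coincide. They do, to ~1e-10 BW RMS across seeds, *provided*
both runs stay on the same equilibrium branch (see path following above).
This is the package's strongest self-consistency check: the kinematic
driving reproduces the kinetic run exactly when fed consistent kinematics.

**The AP surrogate does not close the axial gap.** One acceptance criterion
expects mode D (AP quadriceps surrogate) to be at least as close to mode A in
axial reaction as mode C (no quadriceps). At the defaults this is *false*,
and we ship the red test rather than tune it away. Measured at seed 1, full
resolution: mean axial gap A vs C ≈ 0.06 BW, A vs D ≈ 0.2 BW, and the gap
grows monotonically with `qf_scale` (≈ 0.10/0.13/0.22 BW at 0.25/0.5/1).
The mechanism is visible in the force balance: at the quadriceps peak the
patellar mechanism transmits (−1.42, +0.36, −0.10) BW to the femur — a
posterior pull *plus a proximal lift*. The lift roughly cancels the axial
effect of the posterior component through the plateau slope, keeping A close
to C axially; the surrogate injects the posterior pull without the lift and
overshoots. The surrogate *is* effective where intended — the IE criterion
(modes B/C/D pairwise closer in IE than any is to A, by 0° vs ≈ 3.7°) passes
by a wide margin, and the sweep recovers a synthetic `qf_scale` truth of 0.7
to within grid resolution — but an AP-only force is a poor axial proxy for a
mechanism with a vertical component.

## Problem sizes and budgets

| computation | grid | steps | wall time |
|---|---|---|---|
| full-resolution run (1 mm, ~1550 columns) | default | 100 | 5-8 s per mode |
| coarse run (2 mm, ~380 columns) | tests | 25-50 | 1-3 s |
| round trip, 5 seeds (coarse, 50 steps) | tests | — | ~1.5 min |
| `qf_scale_sweep`, 16 scales (coarse, 25 steps) | tests | — | ~15 s per seed |
| Terzaghi oracle (32 layers, dt = t_char/500) | tests | ~700 | <1 s |

The acceptance suite runs all eight criteria in a few minutes on one CPU; the
mode-contrast criterion runs at full resolution because the contrast is the
headline result.

## Reproducing the headline numbers

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

runs the oracles, the four-mode study at full resolution, the round trip, the
sweep recovery, and the determinism check, and writes every headline quantity
to JSON under descriptive names.
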