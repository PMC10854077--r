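---
title: "Simulating load-induced marrow flow in trabecular bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating load-induced marrow flow in trabecular bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical problem

Cyclic skeletal loading deforms the trabecular lattice of cancellous bone
and pumps the viscous marrow through its pore space.  The fluid shear
stress (FSS) this flow exerts on trabecular surfaces is a central stimulus
in bone mechanobiology: in vitro, osteoblasts respond to FSS of roughly
1–3 Pa, osteoclast precursors migrate towards regions below ~0.1 Pa, and
FSS above ~4 Pa has been associated with osteoblast apoptosis.
`marrowflow` computes, for a millimetre-scale trabecular sample under a
prescribed compressive micro-displacement, the solid stress field, the
marrow velocity field, and the per-face FSS time series on the bone–marrow
interface, together with the derived statistics used to compare
experimental groups (healthy control, diabetic, and four verapamil dose
groups, each with its own tissue modulus and typical bone volume
fraction).

## Model structure and assumptions

The sample is a labelled voxel grid: solid bone (label 1) occupies a cubic
core, marrow (0) fills the core pores, and a margin shell (2) of fluid
surrounds the core so that the open outer boundaries sit away from the
bone.  Default geometry mirrors a typical micro-CT acquisition: 18 µm
voxel pitch, a 0.8 mm solid core (44–48 voxels), and a 2-voxel margin
(the smallest whole-voxel shell covering a ~0.03 mm bath).

Three approximations shape the solvers; each is justified by the scales
involved:

* **Quasi-static solid.**  At 1 Hz and ~0.1 % strain, inertial stresses
  are negligible against elastic ones, so the elastic field at any instant
  is the unit solution scaled by the displacement waveform.  Bone tissue
  is treated as homogeneous, isotropic, linear elastic (E per group,
  ν = 0.3); marrow viscoelasticity and tissue heterogeneity are out of
  scope.
* **Creeping flow.**  With µ = 85.5 Pa·s, velocities of order µm/s and
  pores of order 100 µm, the Reynolds number is ~1e-9: the transient
  Navier–Stokes problem collapses to a sequence of quasi-static Stokes
  problems driven by instantaneous boundary data.
* **One-way coupling on a fixed grid.**  Fluid stresses (a few Pa) are
  ~1e6 times smaller than solid stresses (MPa), so fluid feedback on the
  solid is dropped; wall displacements (≤ 0.8 µm) are far below the voxel
  pitch (18 µm), so walls transmit velocity but the geometry is not
  re-meshed.

Linearity then gives the **superposition fast path**: one unit solid
solve, one wall-driven Stokes mode and one pressure-driven Stokes mode
reconstruct every time step exactly.  The stepwise path (one Stokes solve
per step) is kept and the two are asserted to agree to 1e-6 relative in
the test suite — a strong end-to-end correctness check, since the two
paths exercise different right-hand sides and solver trajectories.

## Boundary conditions

* Bottom core face: fully fixed.
* Top core face: prescribed displacement
  `u(t) = (B/2)(sin(2π(t − T/4)/T) + 1)` along the loading axis
  (B = 0.8 µm, T = 1 s); in-plane components are left free, since only
  the loading direction is physically prescribed.
* Four lateral core faces: spring foundation (Robin condition) acting on
  the **face-normal displacement component only**,
  `traction = −k(u_n − U₀)`.  The literature value k = 16e9 N/mm² per mm
  (1.6e19 Pa/m) makes the lateral faces effectively rigid in their normal
  direction while leaving tangential (axial) motion free.  A vector-valued
  spring of this magnitude would clamp the axial motion of the side faces
  too and destroy the confined-compression limit that a homogeneous cube
  must reproduce (the patch test below); the normal-only reading is the
  one consistent with "support by surrounding bone".  The stiffness and
  its unit string are configuration values and can be overridden.
* Six outer fluid faces: open boundaries.  The prescribed pressure
  `P(t) = (C/2)(sin(2π(t − T/4)/T) + 1)` (C = 667 Pa) enters the normal
  momentum balance as the ghost pressure outside the face, and the
  tangential stress is free.  With equal pressure on all six faces and
  static walls this reproduces hydrostatic equilibrium exactly (zero
  velocity, uniform pressure) — a degenerate case asserted in the tests.
  Note that an equal in-phase pressure on all six faces of an
  incompressible pore space drives almost no flow by itself; the flow and
  the FSS are dominated by the wall-driven mode, which is why the FSS
  peaks at T/4, where the displacement *rate* peaks, rather than at T/2,
  where the displacement peaks.

## Discretisations

**Solid.**  Voxel micro-FE: one 8-node trilinear hexahedral element per
solid voxel, 2×2×2 Gauss quadrature, sparse symmetric assembly, CHOLMOD
supernodal Cholesky.  Dirichlet rows are eliminated; the factorisation is
cached while a geometry is alive.  Element stresses are evaluated at
centroids; the patch test (homogeneous cube, near-rigid lateral springs)
reproduces the constrained modulus E(1−ν)/((1+ν)(1−2ν)) to better than
0.5 %, and with k = 0 and ν = 0 the free-sided uniaxial state is exact to
machine precision.

**Fluid.**  Marker-and-cell (MAC) staggered grid: velocity components on
cell faces, pressures at cell centres.  Unknown faces are those between
two fluid cells or between a fluid cell and the outside; faces between
fluid and solid are no-slip walls carrying the solid's interpolated
velocity (4-node face average).  Tangential no-slip at walls uses
second-order ghost values; tangential stress-free conditions at open
boundaries use reflection ghosts.  The saddle-point system is solved via
the pressure Schur complement: the vector Laplacian block (three decoupled
scalar Laplacians) is factorised once per geometry, and conjugate
gradients run on `D A⁻¹ Dᵀ`, which for Stokes is spectrally equivalent to
a mass matrix — iteration counts stay at 20–90 independent of mesh size.
The CG residual *is* the cell divergence residual, so discrete
incompressibility holds to the solver tolerance (default 1e-10 relative);
global mass balance (outer flux vs wall-displaced volume) closes to
~1e-11 relative in practice.

**FSS extraction.**  Per wall face, the two tangential fluid velocity
components at the adjacent cell centre (half a voxel from the wall) are
differenced against the wall's own tangential velocity:
`τ_t = (2µ/h)(v_t(cell) − v_t(wall))`, and FSS is the magnitude of the two
components.  This one-sided gradient is exact for linear (Couette)
profiles and first-order accurate in general; the `∂v_n/∂t` part of the
full tangential traction is omitted, which is the standard simplification
on staircase voxel walls.  Validation: plane Couette at 16 cells across
reproduces µU/h to < 0.3 %; square-duct Poiseuille reproduces the series
solution's centreline velocity to < 1 % and the global wall force balance
`ΔP·A = τ̄·P_wet·L` to < 0.1 %.

## The synthetic geometry generator

The generator stands in for segmented micro-CT cubes, which are not
shipped with the package.  It emulates the first-order morphometry of
trabecular bone — a connected strut network at a prescribed bone volume
fraction with a characteristic strut scale — but not the anisotropy,
plate/rod mixture, or cortical remnants of real samples.

Procedure (deterministic given the seed):

1. White Gaussian noise on the core grid, smoothed by an isotropic
   Gaussian kernel via FFT (periodic convolution).  The kernel standard
   deviation is half the correlation length; the 120 µm default gives
   strut widths of 3–7 voxels at 18 µm pitch, matching rat trabecular
   dimensions.
2. Threshold at the `(1 − BV/TV)` quantile of the smoothed field.
3. Connectivity cleanup: the solid keeps its largest face-connected
   (6-neighbour) component; pore voxels not face-connected to the outer
   margin (sealed cavities) become solid.  Both phases end as single
   face-connected components — a requirement of both discretisations —
   and the operation is idempotent.
4. Fraction refinement: cleanup removes material, so the solid fraction
   is re-converged by growing the retained component through its
   highest-field pore neighbours (or eroding its lowest-field surface
   voxels) until the core fraction matches the target to within one
   voxel.  Ranking by field value keeps the adjustment isotropic and
   deterministic.
5. Spanning guarantee: near the percolation threshold (~16 % for
   isotropic Gaussian fields) the component frequently misses the top or
   bottom loading face, which would make the elastic problem ill-posed —
   whereas any real load-bearing sample spans by construction.  If a
   loading face is untouched, the highest-field ridge path from the
   component to that face (Dijkstra on the smoothed field) is
   solidified, and the fraction is re-balanced with the bridge protected
   from erosion.

Step 2 alone would miss low targets by up to 0.08 in BV/TV after cleanup;
with steps 4–5 the generator hits all six group levels (12.96 % to
76.8 %) exactly and yields load-bearing geometries for every seed tried.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `B_um` | 0.8 | µm | displacement amplitude (waveform range [0, B]) |
| `T_s` | 1 | s | loading period |
| `C_pa` | 667 | Pa | open-boundary pressure amplitude |
| `k_value`, `k_units` | 16e9, N/mm³ | — | lateral spring foundation stiffness |
| `E_gpa` | 15.08–11.28 | GPa | tissue modulus (per group) |
| `nu` | 0.3 | — | Poisson's ratio |
| `mu_fluid_pa_s` | 85.5 | Pa·s | marrow dynamic viscosity |
| `rho_fluid_g_cm3` | 0.95 | g/cm³ | marrow density (carried, unused by Stokes) |
| `grid_n` | 48 | voxels | core edge |
| `pitch_um` | 18 | µm | voxel pitch (micro-CT resolution) |
| `margin_vox` | 2 | voxels | outer fluid shell thickness |
| `correlation_length_um` | 120 | µm | strut scale of the random field |
| `n_steps` | 20 | — | time samples per cycle |
| `stokes_tol` | 1e-10 | — | relative divergence tolerance |

All quantities are converted once at ingest to SI (m, s, Pa) internally;
user-facing fields use the field's customary µm/MPa/GPa.

## Numerical conventions

* **Quantiles** are linear-interpolation (type 7) everywhere, and field
  standard deviations are population (n) — recorded in outputs.
* **Crop and slice rounding**: sub-cube edges and slice layers round to
  the nearest integer with exact halves toward the lower index, making
  crops bit-reproducible (48 × 0.875 → 42 voxels; half-height of 48
  layers → layer 24).
* **FSS band edges** are half-open `[low, high)` with `[3, ∞)` on top, so
  the four bands partition the interface exactly.
* **Peak detection**: the argmax of the mean-FSS series is refined by a
  parabola through the maximum sample and its cyclic neighbours.  A
  rectified shear series has two humps per period (at T/4 and 3T/4) whose
  heights agree to solver precision; samples within 0.1 % (relative to
  the series range) of the maximum therefore count as tied and the
  earliest wins.  Genuinely distinct peaks differ by far more than the
  tie band at any plausible step count.
* **Seeds**: only the geometry is stochastic.  Batch runs derive
  per-sample seeds deterministically from the configuration seed; the
  generator saves and restores the caller's RNG state.

## Problem sizes

The reference single-sample configuration (48-voxel core at BV/TV 0.30)
solves ~136 000 solid displacement unknowns and ~314 000 fluid face
velocities plus ~105 000 pressures in a few minutes and ~3 GB of memory;
the elasticity factorisation is released before the fluid factorisation
is built so the two never coexist.  Dense solids are costlier: at BV/TV
0.77 and a 48-voxel core the elasticity factor alone exceeds 5 GB.  Batch
group comparisons therefore default to 24-voxel cores (seconds per
sample), which preserve strut-scale resolution — the pitch is fixed — at
a quarter of the physical volume; the trend statistics they feed are
rank-based, not magnitude-based.  The test suite uses 16–32 voxel cores
throughout.

## Known limitations

* The surrogate geometry is an isotropic, single-scale random field.
  Real trabecular bone is anisotropic (struts align with habitual
  loading), mixes plates and rods, and varies in strut thickness;
  group-level morphometric differences beyond BV/TV are not emulated.
* Under displacement-controlled loading of these surrogates, the
  crop-mean FSS at the cycle peak *increases* with BV/TV (Spearman
  ρ ≈ +0.7 across the six group levels): squeezing the same displacement
  through narrower pores raises the wall shear.  Studies of real scanned
  samples have reported the opposite, FSS decreasing with BV/TV — an
  association that plausibly rides on architecture covarying with BV/TV
  in real bone (plate-like closure of pores, changing surface-to-volume
  ratios) rather than on volume fraction alone, and on flow regimes
  closer to pressure-driven perfusion, where shear scales with the
  hydraulic radius and *falls* as pores narrow.  The package reports what
  its model produces; reproducing the real-bone association would require
  scan-derived geometries through `load_voxel_mask()`.
* FSS magnitudes depend on the 18 µm resolution of the near-wall
  gradient; sub-voxel pore features are not resolved.
* The spring-foundation stiffness is so large that lateral faces are
  effectively rigid; results are insensitive to its exact value, and the
  tissue modulus consequently has almost no influence on the fluid fields
  under displacement control (it scales the solid stresses only).
* With three samples per group, the Kruskal–Wallis chi-square p-value is
  approximate; the permutation option exists for exact small-sample
  inference, and outputs carry a small-sample flag.
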