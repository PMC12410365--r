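---
title: "Cell-resolved red blood cell deformation and shear-damage statistics: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-resolved red blood cell deformation and shear-damage statistics: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rbcflow` quantifies mechanical red-blood-cell (RBC) damage in high-shear
flows with a multi-scale, one-way-coupled pipeline: a background flow is
sampled along Lagrangian path lines, the recorded velocity-gradient
histories drive a cell-resolved boundary-integral membrane solver, and the
resulting per-(cell, time) deformation ensembles are reduced to damage
statistics. This vignette documents the models, the numerical choices, and
what the synthetic test conditions do and do not establish.

## The multi-scale decomposition

RBCs (radius a ≈ 2.8 µm) are orders of magnitude smaller than the vessels of
interest (millimetres), and their relaxation time is far shorter than the
flow time scales. Two consequences are exploited:

1. **One-way coupling.** Cells are advected as massless tracers,
   `dx_p/dt = u(x_p, t)`, through a stored flow computed with an effective
   whole-blood viscosity (µ = 4 cP); individual cells do not feed back on
   the macro-scale flow.
2. **Far-field linearization.** At the cell scale the undisturbed flow is
   `u∞(x, t) = U(t) + (x − x_c(t)) · ∇u(t)`: the uniform part translates the
   cell, only the velocity gradient deforms it. The membrane solver
   therefore works in the frame moving with the cell centroid and applies
   the gradient part alone.

The pipeline is `advect()` (tracking) → `advance_cell()` (membrane dynamics
per trajectory) → `summarize_cell()`/`damage_report()` (statistics), with
`run_pipeline()` orchestrating all stages on the synthetic pipe fixture.

## Membrane model

The membrane is a closed 2-D elastic surface. In-plane elasticity follows
the Skalak law, with strain invariants `I1 = λ1² + λ2² − 2` and
`I2 = λ1²λ2² − 1` of the principal stretches λ1 ≥ λ2 measured against a
stress-free reference metric:

W_T = (G/4) (I1² + 2 I1 − 2 I2 + C I2²)

with shear modulus `G = 6×10⁻⁵ N/m` (the strain-hardened high-shear value)
and dilatation ratio `C = 15`. The physical dilatation ratio is O(10⁴);
values above ~10 are known to give converged large-scale dynamics at far
lower stiffness, and C enters the package as a plain parameter. The text
grouping of the published form is ambiguous about whether C sits inside the
`G/4` bracket; the standard Skalak grouping above is used (consistent with C
being the dimensionless ratio of dilatation to shear modulus, e.g. C ≈ 5000
for a dilatation modulus of 0.3 N/m), and the alternative literal grouping
is available via `membrane_material(skalak_grouping = "literal")`.

Bending follows the Helfrich energy
`W_B = (E_B/2) ∫ (2κ − c₀)² dS` with `E_B = 0.95×10⁻¹⁸ J`
(`E_B/(a²G) = 0.002`), mean curvature κ (positive for a sphere with outward
normals) and spontaneous curvature `c₀ = −2/a`.

**Traction sign convention.** The traction jump Δf entering the
boundary-integral equation is the jump in fluid traction across the
membrane, which balances the membrane's internal load. Variationally this is
`Δf = +δE/δx` per unit current area: an inflated sphere carries an outward
Laplace-law traction `2τκ n`, and the single-layer term of the
boundary-integral equation (which enters with a minus sign) then produces
dissipative relaxation. Both tractions are computed as exact analytic
gradients of the *discrete* energies with respect to the spectral
coefficients (a virtual-work construction), so the variational identity
`δE = ∫ Δf · δx dS` holds to round-off by construction and no pole-singular
tensor components are ever expanded in scalar harmonics. Finite-difference
checks of both gradients are part of the test suite.

## Spectral surface representation

The surface map is expanded in real spherical harmonics up to order p
(default 12) for each Cartesian coordinate, collocated on a Gauss–Legendre
(latitude) × uniform (longitude) lattice with `p+1 × 2p+2` points. Nonlinear
quantities (strains, tensions, curvatures) are evaluated on an upsampled
lattice (factor 4 by default) and truncated back to order p — the standard
de-aliasing treatment. Area and volume use the parameter-space quadrature
`∫ f W dθ dφ` with the Gauss–Legendre weights mapped through `1/sin θ`;
both are exact to round-off for band-limited shapes (the test suite checks
spheres at several orders).

**Resting shape.** The biconcave discocyte uses the classical Evans–Fung
profile, uniformly scaled so the enclosed volume is `(4/3)πa³`
(volume-equivalent radius a = 2.82 µm). Its surface area then comes out at
`16.84 a²`, matching the conventional normalization `A₀ = 16.8` (in units of
a²) to 0.3%. The profile is smooth in the latitude parameter and exactly
band-limited at order 5, so the spectral projection is exact at p ≥ 5.

**Reference configuration and material correspondence.** The stress-free
reference is an oblate spheroid "close to a sphere" (aspect ratio 0.9 by
default, configurable; only the qualitative statement is available in the
source literature). Two scalings are provided:

* `make_reference(match = "volume")` (constructor default) encloses the cell
  volume `(4/3)πa³`, the contract the acceptance geometry tests check;
* `make_reference(match = "area")` scales the same spheroid so its area
  equals the biconcave resting area `≈ 16.8 a²`. **All cell dynamics use
  this one.**

The distinction matters and was established numerically. The reference
configuration supplies only the stress-free *metric*; the cytoplasm volume
is conserved by the (incompressible) boundary-integral flow itself, not by
the reference. A volume-matched near-spherical reference has ~25% less area
than the biconcave cell, so the resting membrane would carry areal
pre-strain λ1λ2 ≈ 1.34 everywhere and a dilatational tension of order
`C G I2 ≈ 10 G`. Under that pre-tension every simulated cell deflates to the
near-spherical reference within a millisecond, the shape memory that
produces tumbling at low shear rates disappears entirely, and membrane area
can only *shrink* relative to the resting cell — all of which contradict the
reported cell-scale behaviour this package reproduces (strains starting just
above 1, tumbling below ~2,500 s⁻¹, area dilation at high shear). With the
area-matched reference the resting areal strain is 0.99–1.01 pointwise
(the latitude parameterization of the discocyte is chosen so cumulative area
fractions match the reference spheroid's), the resting shear-strain field
spans 1.0–1.35 — strains "do not start from 1", as expected when the
stress-free state differs from the biconcave — and the classic shear-elastic
shape memory is retained.

Strain baselines at t = 0 depend on the reference aspect ratio; 0.9 is kept
as the package default and is exposed in `run_config()`.

## Boundary-integral solver

With Stokes flow inside and outside, the interfacial velocity satisfies the
second-kind integral equation

u_j(x₀) = 2/(1+λ) u∞_j(x₀) − 1/(4πµ(1+λ)) ∫ Δf_i G_ij dS
        + (1−λ)/(4π(1+λ)) ∫ u_i T_ijk n_k dS,

with the free-space Stokeslet `G_ij = δ_ij/r + r_i r_j/r³`, stresslet
`T_ijk = −6 r_i r_j r_k / r⁵`, and viscosity ratio λ = 1.5 (cytoplasm 6 cP
over blood 4 cP).

* **Singular quadrature.** For on-surface targets the integrals use a
  rotated-pole lattice: the quadrature grid's pole is moved onto the target
  point, so the `sin θ'` of the solid-angle measure cancels the 1/r
  singularity. Gauss–Legendre nodes are placed in θ' itself (not cos θ'),
  because the regularized integrand is smooth in θ' but has a square-root
  structure in cos θ'; this distinction is worth two orders of magnitude in
  accuracy and makes the sphere identities exact to ~10⁻¹³ at modest
  lattice sizes. Per-target evaluation combines precomputed per-latitude
  synthesis matrices with a z-rotation applied as an order-m phase shift in
  coefficient space.
* **Double layer.** The stresslet identity `∫ T_ijk n_k dS = −4π δ_ij`
  subtracts the singularity: the kernel is applied to `u − u(x₀)` and
  `−4π u(x₀)` is restored analytically. For λ ≠ 1 the equation is solved by
  Picard iteration (contraction rate |1−λ|/(1+λ) = 0.2 at λ = 1.5; the
  previous step's velocity is the initial iterate; tolerance 10⁻⁸, cap 200).
  λ = 1 short-circuits to the explicit solution.
* **Time stepping.** Explicit Euler (optional midpoint) on the spectral
  coefficients with re-projection each step. A mild high-mode filter
  (`exp(−s((l−l₀)/(p−l₀))⁴)` above `l₀ = 2p/3`, default strength 0.1)
  controls aliasing noise. The default step size is 10⁻⁵ s; the stable
  explicit step for strongly strained states scales like `µa/(G C I2 p)`,
  so the scaled-down runs in the tests use 1–2×10⁻⁶ s.
* **Volume correction.** The continuous flow conserves the enclosed volume
  exactly; the explicit-stepping drift is removed by a uniform rescale each
  step (`volume_correction = TRUE`), keeping cytoplasm volume at its initial
  value to round-off. Without it the drift is a few percent over a strong
  start-up transient.
* **Stability monitor.** A run is flagged unstable on non-finite
  coordinates, area growth beyond 3× resting, or a spectral-tail energy
  fraction (top two degree bands) above 0.1; unstable cells are excluded
  from all statistics (with counts logged), mirroring the exclusion
  practice at the documented stability bound Ca ≈ 10.85.

**Solver validation.** Beyond the kernel identities, the steady in-plane
Taylor deformation of an initially spherical Skalak capsule (C = 1, λ = 1)
at Ca = 0.6 computes to D ≈ 0.43, in the range published for spectral
boundary-integral capsule codes. Tank-treading above and tumbling below the
~2,500 s⁻¹ threshold at λ = 1.5 are reproduced with the area-matched
reference (see the acceptance tests); the regime classifier tracks the
thickness (smallest-covariance) axis, which is non-degenerate for disc-like
shapes, plus the lab-frame circulation of a marked membrane material point.

## Background flows and tracking

* **Stored fields** are tetrahedral meshes with per-node velocity frames
  uniformly sampled over one period. Continuous nodal gradients come from an
  L2 projection of the element-wise constant gradients (lumped mass by
  default, consistent mass optional; both exact for affine fields). Temporal
  reconstruction uses the full trigonometric interpolant of the stored
  frames (all modes retained, even Nyquist as a pure cosine), which is exact
  at the sample times, exactly periodic, and preserves nodal time means.
* **Tracking** is forward Euler at Δt = 5×10⁻⁵ s (default) over 3 periods,
  with host elements located through uniform search boxes (every element is
  listed in each box its bounding box overlaps; ties on shared faces resolve
  to the lowest element id). Outlet crossings retire the particle; wall
  crossings are reflected specularly about the crossed boundary triangle
  (closest wall node → first-ring faces → segment-triangle intersection,
  nearest-face fallback), preserving the displacement length.
* **Seeding** distributes a per-cycle particle budget over time steps in
  proportion to the inlet volume influx (largest-remainder rounding, zero
  during bulk backflow) and places particles on the inlet with probability
  proportional to the local inward normal velocity, so the seeded number
  density tracks the volume flux as a uniform hematocrit requires.

The tracking validation (10,000 particles in an analytic Hagen–Poiseuille
flow at Δt = 5×10⁻⁵ s) reports the maximum particle-velocity error as a
fraction of the peak (centreline) speed; the measured value on the fixture
mesh (in-plane edge R/40) is ≈ 0.03%, against a 0.1% acceptance bound. The
error normalization is by peak speed — relative-to-local error is unbounded
at the wall where the profile vanishes, so a bulk scale is the only
well-posed choice; this reading is documented rather than specified by the
source.

## Damage statistics

Each (cell, time) pair is one ensemble member (`DeformationRecord` rows).
From the records:

* `strain_pdfs()` — normalized histograms (integral 1) of max/mean areal and
  shear strains and the global shape ratios A/A₀, L/L₀ (A₀, L₀ from the
  package's own resting shape, self-consistent with the `16.8 a²`
  normalization).
* `classify_damaged()` — a cell is damaged under a (criterion, threshold)
  pair iff its *per-cell peak* meets the threshold (fractions are
  percentages of cells, which is why the peak reading rather than a
  per-instant reading is adopted); thresholds default to the literature
  ranges L/L₀ ∈ {1.75, 2, 2.25}, λ1/λ2 ∈ {2.5, 3, 3.5}, ΔA/A₀ ∈
  {10, 12, 14}%.
* `instances_per_damaged()` — exposure counting: mean number of recorded
  exceedances per damaged cell (absent, not zero, when no cell is damaged).
* `cell_damage_index()` — CDI = (1/n_RBC) Σ_cells Σ_times |e|^α Δt_i with
  excess e = (A−A₀)/A₀, (L−L₀)/L₀ or λ1/λ2 − 1. The absolute value is
  deliberate (the index accumulates deviation from baseline, so excursions
  below baseline contribute); α ≥ 1 weights extreme events, and α is left
  free because the empirical power-law exponent spans ~2.0–2.4.
* `residence_time()` — mean in-domain (or in-region) time; the source is
  ambiguous about whether the window is the whole domain or the high-shear
  region only, so the default is total in-domain time with an optional
  element-subset region.
* `damage_map()` — per-vertex metric values on path lines, exported as VTK
  polylines; cross-run colour scales are a downstream plotting choice.

`subsample_trajectories()` reduces a tracked cohort to the cell-simulation
budget by stratified sampling over quantile bins of per-trajectory mean
shear rate, keeping the pooled shear-rate histogram within a 2.5% sup-norm
deviation (the documented bound on distribution shift from exclusions).

## Synthetic study conditions

The fixture generator defines the test conditions: a cylindrical pipe
(tet mesh with labelled inlet/outlet/wall), pulsatile Poiseuille frames
`u = U_max w(t) (1 − r²/R²) e_z` (the `"pulsatile"` waveform is a
cardiac-like harmonic series with ~1/k² amplitude decay, chosen so that
halving the stored frame count changes the reconstruction by a small but
nonzero amount), and shunt-passage-like shear histories: baseline
10³ s⁻¹ with millisecond-scale cosine-tapered excursions to 4×10⁴ s⁻¹
(Ca from 0.188 to 7.52 under the default material). Fixture generation is
deterministic given parameters and seed.

**Problem sizes used by the tests** (chosen as desk-scale renditions of the
study conditions): the steady high-shear check runs at order 10 with
Δt = 10⁻⁶ s to t = 0.7 ms, the regime runs at order 8 with Δt = 1–4×10⁻⁶ s
and horizons up to 1.6 ms; the tracking validation uses the full 10,000
particles for 200 steps on a ~690k-element mesh; the end-to-end pipeline
smoke test tracks tens of particles and simulates a handful of cells.
A resolution study of the steady tank-treading state at Ca = 7.52
(Δt = 10⁻⁶ s, t = 0.7 ms) gives global area dilation / elongation of
5.9% / 95% at order 8, 6.2% / 97% at order 10, and 6.4% / 98% at order 12:
both metrics converge upward, and the order-10 values are within one
percentage point of the production-order (12) ones.
What passing these tests shows: the solver reproduces closed-form membrane
mechanics, kernel identities, literature-range capsule deformation, the
qualitative motion regimes, and the statistics layer agrees with brute-force
recounts on synthetic cohorts. What they do not show: anatomy-scale damage
fractions (Tables of damaged-percentage values over hundreds of cells in
patient-like geometries require the full CFD campaigns, which are outside
the package's scope), or absolute hemolysis prediction — the damage indices
are relative comparators by construction.

## Known limitations

* One-way coupling and free-space Green's functions: no wall-bounded
  kernels, no cell–cell interactions (effective-medium viscosity only).
* Fixed topology: no pore formation, rupture or fragmentation; runs that
  head that way are flagged unstable and excluded, never reinterpreted.
* The steady high-shear deformation level depends on the unreported
  reference-spheroid details (aspect ratio, area matching); the package
  documents its choices and exposes them as parameters rather than claiming
  a unique reconstruction.
* Explicit time stepping keeps the implementation transparent but makes the
  stable step size shrink as `1/(C γ̇)` at large strains; the acceptance
  runs use reduced resolution and horizons accordingly.
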