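# rbcflow

Cell-resolved modelling of mechanical red-blood-cell (RBC) damage in
high-shear flows, for researchers comparing cardiovascular geometries or
blood-wetted devices by the deformation loads they impose on cells.

High-shear regions downstream of surgical connections (for example the
aorto-pulmonary shunts of the stage-one single-ventricle palliation) expose
RBCs to shear rates far above the physiological range, driving sublethal
membrane damage and hemolysis. `rbcflow` implements the full cell-scale
chain needed to quantify that exposure:

* **Membrane mechanics.** The RBC membrane is a spectral
  (spherical-harmonic) surface carrying the Skalak in-plane law
  `W_T = (G/4)(I1² + 2 I1 − 2 I2 + C I2²)` and the Helfrich bending energy
  `W_B = (E_B/2) ∫ (2κ − c₀)² dS`, with defaults `G = 6×10⁻⁵ N/m`,
  `C = 15`, `E_B = 0.95×10⁻¹⁸ J`, `c₀ = −2/a`, `a = 2.82 µm`.
* **Fluid–structure coupling.** The interfacial velocity solves the
  boundary-integral (Stokes) equation
  `u = 2/(1+λ) u∞ − 1/(4πµ(1+λ)) ∫ Δf·G dS + (1−λ)/(4π(1+λ)) ∫ u·T·n dS`
  with viscosity ratio λ = 1.5, a rotated-pole singular quadrature, and
  explicit time stepping of the spectral coefficients.
* **Lagrangian tracking.** Massless tracers advected through analytic or
  stored time-periodic tetrahedral flow fields (Fourier temporal
  reconstruction, L2-projected nodal velocity gradients, search-box host
  lookup, flux-weighted inlet seeding, specular wall reflection), recording
  the velocity-gradient history `∇u(t)` and shear rate
  `γ̇ = (∂_j u_i ∂_j u_i)^{1/2}` each cell experiences.
* **Damage statistics.** Per-(cell, time) ensembles feed strain PDFs,
  damaged-cell fractions under literature thresholds (elongation L/L₀,
  mean shear strain λ₁/λ₂, area increment ΔA/A₀), exposure-instance counts,
  and the cell damage index
  `CDI = (1/n_RBC) Σ_cells Σ_t |e(t)|^α Δt` with excess `e` in area,
  elongation, or shear strain.

Everything runs on synthetic fixtures generated in code (a labelled
cylindrical-pipe tet mesh, pulsatile Poiseuille frames, shunt-passage-like
shear histories), so the whole pipeline is testable without external data.

## A worked example

Simulate one cell through a shunt-passage-like shear history (baseline
10³ s⁻¹, a millisecond excursion to 4×10⁴ s⁻¹) and summarize it:

```r
library(rbcflow)

a <- 2.82e-6
mat <- membrane_material(a = a)         # cell-resolved default parameters
ref <- make_reference(a, 0.9, match = "area")
cell <- make_resting_rbc(a, order = 8)

prof <- shear_history_profile(baseline = 1e3, peak = 4e4,
                              pulse_start = 5e-4, pulse_duration = 5e-4)
hist <- make_shear_history(prof, duration = 2e-3, dt = 1e-5)

res <- advance_cell(cell, ref, mat, hist, dt = 1e-6, record_stride = 50)
glance(res)
#> # A tibble: 1 x 7
#>   stability  t_end volume_drift peak_length_ratio peak_area_ratio
#>   <chr>      <dbl>        <dbl>             <dbl>           <dbl>
#> 1 stable   0.00200      8.88e-16              2.09            1.05
#> # i 2 more variables: peak_max_shear_strain <dbl> (4.15), peak_Ca <dbl> (7.52)
```

`peak_Ca` reaches 7.52 during the excursion (`Ca = µ γ̇ a / G`); the cell
elongates to ~2.1× its resting length, the maximum local membrane shear
strain reaches ~4.2 and the surface area dilates ~5% at the pulse peak
before recovering toward baseline, while cytoplasm volume is conserved to
round-off. Reduce a cohort of such runs to the damage tables with:

```r
records <- summarize_cell(res)
report <- damage_report(records)
tidy(report)       # damaged fractions + exposure instances per threshold
report$cdi         # cell damage index per metric and exponent
autoplot(report)   # ensemble strain PDFs
```

The end-to-end fixture pipeline (seed → track → simulate cells → damage
report, with artifacts written to a directory) is a single call:

```r
out <- run_pipeline(run_config(seed = 1), out_dir = "run1")
print(out$report)
```

A thin command-line front end over the same functions lives at
`inst/cli/rbcflow` (subcommands `fixtures`, `track`, `simulate-cells`,
`damage`, `run-all`).

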