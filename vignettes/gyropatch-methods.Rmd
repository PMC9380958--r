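---
title: "Modelling gyrotactic microbe patchiness in turbulent mixed layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gyrotactic microbe patchiness in turbulent mixed layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(gyropatch)
```

## The scientific problem

Many phytoplankton and other motile microbes are *gyrotactic*: a bottom-heavy
cell experiences a gravitational restoring torque that biases its swimming
direction toward the upward vertical, while the viscous torque of fluid
vorticity overturns it. When these torques are comparable, theory and
idealised simulations predict that swimmers focus into intense microscale
patches — with consequences for grazing, infection, competition and the
spatial structure of primary production. Whether this mechanism survives in
*realistic*, depth-structured, unsteady turbulence — such as a convective
mixed layer cooled from above — is the question this package is built to
explore at desk scale.

`gyropatch` provides the full chain:

1. **Velocity fields** — analytic test flows, a synthetic kinematic-turbulence
   generator with a convective mixed-layer depth structure, and a reader for
   gridded netCDF velocity snapshots (e.g. pre-computed DNS output).
2. **An individual-based model (IBM)** — `N` microbes whose swimming
   direction `p` follows
   `dp/dt = (1/2B)[k − (k·p)p] + (1/2) ω × p`
   (forward Euler with renormalisation) and whose position follows
   `dX/dt = v_swim p + u(X, t)` (classical RK4 with `p` frozen across the
   substeps), with periodic horizontal boundaries and reflective walls at the
   surface and bottom.
3. **Patchiness statistics** — periodic 3D Voronoi tessellation, local
   concentrations (inverse cell volumes), `f`-fraction patch selection, and
   the patch concentration enhancement factor
   `Q = (C − C_P) / C_M`,
   the median patch concentration of motile cells minus that of passive
   tracers, normalised by the overall concentration.
4. **Diagnostics** — Kolmogorov scales `η_K = (ν³/ε)^{1/4}`,
   `τ_K = (ν/ε)^{1/2}`, `u_K = (νε)^{1/4}`; the stability number
   `Ψ = B√(ε/ν)` and swimming number `Φ = v_swim/(νε)^{1/4}`; convective
   mixed-layer scales `w* = (F_b h₀)^{1/3}`, `Re = w* h₀/ν`,
   `Ri₀ = h₀ Δb / w*²`; effective velocities; orientation statistics.

The default physical configuration is a 0.6 × 0.6 × 0.3 m horizontally
periodic tank with the surface at `z = 0.3` m, viscosity `ν = 5×10⁻⁶ m²/s`,
surface buoyancy flux `5×10⁻⁴ m²/s³` over a 0.15 m mixed layer
(`w* ≈ 0.042 m/s`, `Re ≈ 1260`), and the standard IBM protocol: `Δt = 0.01 s`,
60 s of simulation, output every 0.1 s, microbes seeded uniformly in the
upper half with uniformly random orientations, and the motility grid
`B ∈ {1, 3, 5} s × v_swim ∈ {10, 100, 500} μm/s` against one non-motile
baseline.

```{r scales}
scale_report(nu = 5e-6, epsilon = 2.66e-4, B = 1, v_swim = 500e-6,
             F_b = 5e-4, h0 = 0.15)
```

## The synthetic turbulence generator

A DNS of convective mixing cannot be rerun casually, so
`make_kinematic_turbulence()` builds a *kinematic simulation*: a sum of
random Fourier modes with a prescribed energy spectrum (default slope −5/3),
eddy-turnover unsteadiness frequencies `ω_n ∝ √(k_n³ E_n)`, and a depth
envelope that reproduces the qualitative structure of a surface-cooled mixed
layer — turbulence strongest near the surface, declining with depth, and
exactly quiescent below a density interface near `z ≈ 0.105–0.165` m. The
target surface rms speed (default 0.04 m/s, the order of the convective
scale `w*`) is calibrated by Monte-Carlo sampling at construction.

Three constructional choices matter and are deliberate:

* **Exact incompressibility, envelope included.** The field is built as the
  curl of an enveloped vector potential, `u = ∇×(g(z) A(x, t))`, rather than
  by multiplying a solenoidal field by `g(z)` (which would leave an `O(g′)`
  divergence error). Divergence-free advection is what guarantees passive
  tracers do not cluster, which is the null hypothesis every patchiness
  statistic is measured against — it must hold exactly.
* **A material surface.** Every mode carries a z-mirrored partner
  phase-locked at the surface, so the vertical velocity vanishes identically
  on `z = Lz`. Without this the synthetic flow penetrates the reflective
  boundary that the IBM applies to microbes, and reflecting tracers across a
  plane the fluid crosses folds fluid volumes — manufacturing spurious
  concentration caustics throughout the turbulent layer (we observed null-control
  Q magnitudes of order 10⁵ before this correction). The side effect is
  physical: near the surface, vertical variance transfers into the
  horizontal components, the classic free-surface signature, and exact
  per-component isotropy holds only in the interior.
* **Tetrahedral mode shells.** Wavenumber magnitudes are geometrically
  spaced in shells of four modes whose directions form an independently
  rotated tetrahedron. A tetrahedron's direction second moment is exactly
  isotropic, so every shell feeds the three velocity components equally
  *regardless of how steep the spectrum is* — with iid directions the few
  energetic low-k modes dominate and component variances fluctuate by tens
  of percent from seed to seed.

The envelope itself is a C² quintic smoothstep from exactly 0 below the
interface to 1 above it, times a linear decline (default 50%) from the
surface down to the interface top. The compact support makes the deep water
*exactly* quiescent, and the tilt reproduces the monotone decay of turbulent
kinetic energy with depth; a flat plateau would make depth-monotonicity
checks hostage to sampling noise.

```{r profile, fig.height = 4}
kf <- make_kinematic_turbulence(n_modes = 32, seed = 1)
prof <- turbulence_profile(kf, z_levels = seq(0.05, 0.3, by = 0.025),
                           nu = 5e-6, n_samples = 1000, seed = 1)
autoplot(prof)
```

What the generator does *not* emulate: coherent convective plumes and their
large-scale up/down asymmetry, mixed-layer deepening, buoyancy and
temperature dynamics, and realistic two-point statistics beyond the energy
spectrum. Tests that pass against this surrogate demonstrate the *machinery*
(integration, tessellation, statistics) and the *mechanism* (torque-balance
clustering), not quantitative agreement with any particular DNS.

## Numerical choices

* **Schemes.** Positions use classical RK4 (observed order ≥ 3.5 on analytic
  vortices); orientations use forward Euler with renormalisation to unit
  length after every step (the continuous equation preserves `|p|`, the
  discrete one does not). The orientation is updated first each step from
  the vorticity at the pre-step position, then held frozen through the RK4
  substeps — the two schemes are only first-order consistent jointly, which
  is the standard operator-splitting trade-off.
* **Boundaries.** Horizontal wrap, reflective surface and bottom. The bottom
  wall is unreachable in practice (microbes are seeded above a quiescent
  layer ~0.1 m thick and 60 s is far too short to sediment through it); it
  exists for closure. Orientation is not flipped on reflection; the top cell
  layer is excluded from patch analysis anyway.
* **Degenerate inputs.** Duplicate tessellation generators are an error
  naming the offending pair; empty patch pools yield missing values, never
  zeros; `ε = 0` gives infinite Kolmogorov timescale and an undefined (`NA`)
  swimming number; a zero effective velocity has magnitude 0 and missing
  angles.
* **Ties.** Patch selection takes exactly `⌈fN⌉` indices, ties broken by
  stable index order.
* **Determinism.** One seeded generator per simulation, positions drawn
  before orientations, microbe-major; field construction restores the
  caller's RNG state. Identical seeds give bit-identical trajectories and
  byte-identical exported CSVs. A compiled stepping kernel (used for
  uniform, vortex-array and kinematic flows) and the reference R
  implementation agree to ~10⁻¹³ per step; each is individually
  deterministic.

## The Q statistic and its conventions

At each analysis time (default cadence 1 s) each ensemble is tessellated
separately, excluding microbes above `z_excl` (default: the domain height
minus one 1/360 cell layer, mirroring the exclusion of the top grid layer of
a 720×720×360 reference grid). Patches are the fraction `f = 0.01` of
microbes with the smallest Voronoi cells, selected globally and then
attributed to depth regions — `Shallow` [0.24, 0.30] m, `Mid` [0.17, 0.24) m,
`Deep` [0.10, 0.17) m by default. A per-region selection variant is
available behind the `selection` switch, as is a pooled single-region
analysis (`regions = NULL`). The normalisation is `C_M = N / V_eff` with
`V_eff` the domain volume below the exclusion ceiling; this makes `Q = 0`
exact for identical ensembles and antisymmetric under swapping the
ensembles, and the value used is recorded on the returned object. A region
needs at least 5 patch members from each ensemble at a time for a valid Q;
otherwise the value is missing rather than a median of near-singletons.
Negative Q is legal and means motile patches are *less* concentrated than
passive ones.

The Voronoi volumes themselves come from a compiled half-space clipping
tessellator (horizontal minimal-image periodicity, planar z walls) validated
against an independent grid-counting oracle; volumes tile the domain to
~10⁻¹⁵ relative.

## The desk-scale study designs

These are the configurations the test-suite and the acceptance script run;
sizes are chosen to make each check statistically decisive at desk scale.

**Steady vortex-array mechanism study.** The headline qualitative claim —
swimmers that balance reorientation against overturning (`Ψ ≈ 1`) cluster,
slow clumsy swimmers do not — is tested in a steady Taylor–Green vortex
array tuned so `Ψ = B U κ = 1.000` for the agile population
(`B = 1 s, v_swim = 500 μm/s`). Two geometric constraints drive the design:
the Voronoi statistic can only resolve aggregation if many microbes share a
vortex, and trapping requires the swim speed to be a large fraction of the
flow speed (we use `v_swim/U = 0.9`; above 1 cells outswim the vortices and
pile at the surface instead). Both are met in a cubic domain of side
`π/100 ≈ 0.0314` m with `κ = 1800 rad/m` (9 vortex periods across, 18 rows
deep), `U = 1/1800 m/s`, `N = 5000`, 60 s. The non-agile population
(`B = 5 s, Ψ = 5, v_swim = 10 μm/s`) is kinematically almost a tracer. In
this configuration agile swimmers reach time-mean Q of order +30 while
non-agile swimmers stay near 0, an ordering stable across seeds. At the
full 0.6 × 0.6 × 0.3 m tank scale the same mechanism operates but its
aggregates are far smaller than the inter-microbe spacing of desk-scale
ensembles, so no Voronoi-based statistic can detect them — the domain is
scaled, not the physics.

**Null control.** Two independently seeded non-motile ensembles
(`N = 5000`, 20 s) advected through the same kinematic field must show no
systematic patch enhancement: the time-mean Q per region stays within 3
block-bootstrap standard errors of zero (block length 5 to respect the ~
seconds-scale autocorrelation of the series).

**Demo experiment.** `demo_experiment_config()` runs the full pipeline —
kinematic flow, non-motile baseline plus one agile gyrotactic population,
Q series, scale report, effective velocities, polar angles, manifest and log
— with 2000 microbes for 30 s in a few minutes on one CPU.

## Known limitations

* The synthetic flow is a surrogate: quantitative Q magnitudes from the
  convective-DNS study (time-mean deep-region Q ≈ 0.27, peaks ≈ 1.6, the
  ~12 mm/s effective-speed boost) depend on the DNS fields and are not
  reproduced here; only signs, orderings and scale relations are.
* No run-and-tumble, rotational diffusion, chemotaxis, cell–cell
  interactions or feedback on the flow; cells are spheres with a fixed `B`
  and `v_swim`.
* Patch *lifetimes* are not estimated; the Q series quantifies instantaneous
  enhancement only.
* The reflective surface with position-only reflection is a closure, not a
  model of real surface behaviour; analyses exclude the top cell layer.
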