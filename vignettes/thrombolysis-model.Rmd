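---
title: "The clotlysis thrombolysis model: kinetics, microstructure, transport and flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The clotlysis thrombolysis model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clotlysis)
```

This vignette is the package's own account of the science it implements: the
model equations and their assumptions, the parameters that matter and how
their defaults were fixed, the numerical choices, and what the shipped
simulations do and do not demonstrate about real thrombolysis.

## The biochemical system

Therapeutic thrombolysis dissolves an occluding fibrin clot by infusing
tissue plasminogen activator (tPA). tPA is fibrin-specific: it must adsorb
onto the fibrin surface together with plasminogen (PLG) before it can
activate plasminogen into plasmin (PLS), the protease that actually cleaves
fibrin. The package models the three proteins in two phases per location —
free (`C_α`, µM, in the pore fluid or plasma) and bound (`S_α`, µM per clot
volume, on the fibrin surface):

* **Adsorption/desorption** with Langmuir saturation of a finite
  binding-site density `θ_α`:
  `A_α = k_ads,α C_α (θ_α − occupied_α) − k_rev,α S_α`. tPA has its own site
  class; plasmin is generated on, and occupies, plasminogen sites, so PLG
  and PLS compete for one shared class. That sharing convention follows the
  Diamond–Anand lineage of fibrinolysis models and is configurable.
* **Plasmin generation** on the surface by Michaelis–Menten kinetics:
  `G_PLS = k₂ S_tPA S_PLG/(K_M + S_PLG)`.
* **Lysis**: `dL/dt = (k_cat/γ) S_PLS`, where `L` (µM) is lysed fibrin,
  `n₀` the initial fibrin concentration and `γ` the number of plasmin cuts
  needed per fibrin unit.
* **Solubilization**: as the supporting fibrin dissolves, bound protein is
  returned to the free phase at rate `κ S_α (dL/dt)/(n₀ − L)`. With `κ = 1`
  this makes `S_α` decay exactly in proportion to the remaining fibrin, so
  no bound protein survives complete lysis — the same guarantee the
  binding-site density provides, since `θ_α ∝ n₀ − L`.
* **Inhibition**: free plasmin is quenched by α₂-antiplasmin,
  `rate = k_AP C_AP C_PLS`, forming an inert 1:1 complex. Because almost all
  plasmin stays surface-bound, inhibition barely affects the lysis time;
  the spatial tiers therefore drop AP and track only tPA/PLG/PLS.
  Plasminogen-activator inhibitor and α₂-macroglobulin are outside the
  model's scope.

## The well-mixed tier and the plasma pool

`simulateWellMixed()` integrates the system with deSolve's `lsoda`
(adaptive, stiff-capable — the solubilization term stiffens as `L → n₀`,
which is why the paper-standard explicit Runge–Kutta is not used here; all
checks are on outputs, not the integrator).

A structural point: the free phase is a stirred **plasma pool** of
`plasma_volume_ratio` (V_r) clot volumes plus the clot's pore fluid, and the
solved variable is the pooled amount `F_α = (V_r + ε) C_α` per clot volume.
A closed clot-only system (V_r = 0, i.e. the superficial concentration
`ε C_α`) cannot reproduce the benchmark equilibrium this model family is
calibrated to — 2 µM total plasminogen partitioning into 1.65 µM free and
34.9 µM bound per clot volume — because the bound inventory exceeds what one
clot volume of plasma holds by two orders of magnitude. The same benchmark
pins the pool size: mass balance requires `V_r + ε₀ = 34.9/(2 − 1.65)`,
giving V_r ≈ 98.7. This also explains why free tPA and PLG drift only
slightly during lysis while the bound phases swing by tens of µM. Setting
`plasma_volume_ratio = 0` recovers the closed-system equations exactly, and
the conservation tests exercise both limits.

## The fibrin microstructure model

Lysis is treated as homogeneous shrinkage of the fibre radius (not lateral
transection): fibrin mass per unit fibre length scales with the
cross-section, so

* `R_f(L) = R_f0 √(1 − L/n₀)`;
* voidage `ε = 1 − (1 − ε₀)(R_f/R_f0)²`;
* binding sites `θ_α = θ_α0 (R_f/R_f0)^q` with `q = 2` by default (sites
  proportional to remaining fibrin mass). `q = 1` (surface-area scaling) is
  exposed via `theta_exponent` because the scaling exponent is a modelling
  choice, not an observable, at this level of description;
* permeability by the Davies correlation for fibrous beds,
  `k = R_f²/(16 φ^1.5 (1 + 56 φ³))`, `φ = 1 − ε`, capped at `k_max`
  (default 10⁻⁶ m²) because the true permeability diverges as the clot
  vanishes. Cells at or above `voidage_lysed_threshold` (default 0.9999)
  additionally lose their Darcy resistance entirely, so lysed cells recover
  unobstructed flow. The correlation is pluggable (`permeability_fn`).

## Parameter defaults and how they were fixed

Reference conditions: fibrin density 0.28 mg/ml, fibre radius 250 nm,
fibrin monomer 340 kg/mol (so `n₀ = 0.824` µM, and the 2 mg/ml assay clot is
the familiar 5.88 µM), inlet/pool concentrations 50 nM tPA and 2 µM PLG,
1 µM antiplasmin.

Adsorption constants use literature dissociation constants of the
Diamond–Anand model family (tPA 0.58 µM, PLG 2.2 µM, PLS 0.57 µM, with
`k_ads = 0.1` µM⁻¹s⁻¹). Two quantities are deliberate calibrations, fixed
once against the model family's published benchmarks and not revisited:

* `binding_sites_per_monomer["PLG"]` (≈ 98.9, i.e. `θ_PLG0 ≈ 81.4` µM) is
  set so that the 2 µM plasminogen pool equilibrates to exactly
  1.65 µM free / 34.9 µM bound via the Langmuir isotherm.
* `k₂ = 1.5` s⁻¹ and `k_cat = 1.3` s⁻¹ (with `γ = 160`) are set so the
  reference well-mixed run completes (99%) lysis at ≈ 90 s, the benchmark
  completion time for these conditions, with bound plasmin peaking at a few
  µM — the magnitude that makes it visible next to the 34.9 µM bound-PLG
  trajectory. The validation configuration (`K_M = 2.42` µM,
  `k₂ = 0.22` s⁻¹, 5.88 µM fibrin) instead matches published assay
  conditions and is used for the dose–response shape check.

The **initial voidage** requires a fibre-internal fibrin concentration that
is not observable at this level of description. The default (11.2 mg/ml,
`φ₀ = 0.025`, `ε₀ = 0.975`) was chosen so the Davies correlation yields
`k₀ ≈ 1.0e-12 m²`, inside the measured range for fibrin gels of comparable
density. This matters physically: at a 1 Pa pressure drop the resulting
permeation velocity through the intact 2.5 mm occlusion is ≈ 0.1 µm/s, so
pre-breakthrough transport is genuinely diffusion-limited (cell Péclet < 1),
which is the regime the whole occlusion story assumes. Taking instead a
protein-dense fibre (~0.28 g/ml) would give ε₀ = 0.999 and k₀ ≈ 1e-10 m²,
making permeation dominate from the start — inconsistent with the model's
own premise.

Diffusivities default to 5×10⁻¹¹ m²/s for all three species, the
free-solution order of magnitude for ~60–90 kDa plasma proteins. No tuning
was applied: with this value the 1D front velocity lands at 22 µm/min,
inside the 20–50 µm/min range reported across experimental and
computational studies.

## 1D diffusion-limited transport

`simulate1D()` uses the classical explicit scheme (second-order central
diffusion, first-order forward time) with a CFL safety factor of 0.4 on the
diffusive bound, and sub-steps the kinetics (default 0.02 s) inside each
transport step; the per-cell state advances in compiled code. The clot
(default 3 mm, with a 0.1 mm fluid gap at the inlet so the boundary does not
sit on the clot face) starts plasminogen-equilibrated; the inlet holds
50 nM tPA / 2 µM PLG fixed and the outlet is zero-gradient. Bound species
are not transported.

The tier reproduces the expected front phenomenology: a bound tPA/PLS peak
that travels with the 95%-lysis front, becoming shorter and wider as free
tPA tends to spatial uniformity; near-constant front speed after an initial
acceleration (position–time R² > 0.99 over 10–80 min); and a dose–response
that rises monotonically from 1 nM to 1 µM tPA with logarithmically
diminishing increments. Front width trends are measured with interpolated
half-maximum crossings (`peakMetrics()`) so grid quantisation does not alias
them, and the approach to uniformity is measured by the coefficient of
variation (the raw spatial variance still grows while the domain fills).

## 2D flow and coupled transport

`solveFlow()` solves steady volume-averaged momentum + continuity in
superficial-velocity form — one equation valid in open fluid and clot, with
the Darcy sink `−(µ/k)u` active in clot cells — on a staggered MAC grid with
fixed inlet/outlet pressures and no-slip walls. The discrete system
(velocities and pressure together) is row-equilibrated and factorised by a
sparse direct LU; the first-order upwind convective term is converged by
relaxed Picard iteration on the right-hand side. This monolithic quasi-steady
formulation replaces pseudo-transient projection marching: the lysis time
scale (minutes–hours) dwarfs the flow relaxation time, so only the steady
flow between lysis increments is ever needed, and a direct solve delivers it
with machine-accurate continuity (the oracle suite checks plane Poiseuille
to < 2% L², the Darcy limit to < 5%, and cell-wise divergence at round-off).
Blood is Newtonian with ρ = 1050 kg/m³, µ = 3.5 mPa·s. Inertial
(Forchheimer) clot resistance and turbulence are omitted.

`simulateOcclusionLysis()` couples this to species transport with operator
splitting: free species advance by a backward-Euler implicit step (upwind
advection + central diffusion of the superficial concentration `ε C`,
advected with the superficial velocity for consistency with the
volume-averaged storage term), kinetics advance by explicit sub-steps, and
the flow is re-solved — warm-started, with the accumulated `−∂ε/∂t` as a
continuity mass source — whenever any cell's voidage has drifted by more
than 0.01 since the last solve. The implicit transport operator is
factorised once per flow update and reused, which is what makes the
post-recanalization phase (advective CFL times of milliseconds over
thousands of seconds) tractable; the step is capped at twice the advective
CFL time, trading some front sharpness (first-order upwind already diffuses)
for speed. Breakthrough bookkeeping follows the breakthrough-ratio (BTR)
definition: time zero when the first cell reaches 1% lysis, breakthrough
when a clot-exit-column cell passes 95%, ties broken by earliest recorded
time. Event detection has the resolution of the recording cadence
(`metric_dt`, default 10 s).

## Problem sizes and the scaled occlusion scenario

The shipped `occlusion-*Pa` scenarios use the full geometry (5 mm channel,
2.5 mm clot, run-out lengths of 5 and 10 clot widths) at 160×40 cells — a
deliberate reduction from the mesh-independent resolutions commercial CFD
would use, with `buildChannel(nx, ny)` as the convergence-study hook. The
test suite and the acceptance script run the `occlusion-scaled-*`
variants — 1 mm channel, 0.5 mm clot, 80×20 cells — chosen so that one full
lytic history (diffusion-limited onset → breakthrough → BTR 1.5) completes
in tens of seconds of compute. The scaling preserves the regime sequence
(diffusion-limited at 1 Pa, Péclet < 1, then convection-dominated after
breakthrough) but lowers the post-canalization Reynolds number roughly an
order of magnitude relative to the full geometry; consequences below.

In the scaled runs the qualitative picture matches the full model's
narrative: lysis starts at the clot centreline, digs a funnel-shaped canal
widest at the proximal face; at 1 Pa the lysed region stays mirror-symmetric
through BTR 1.5; breakthrough time falls steeply and monotonically with the
imposed pressure drop (1210/430/270/180 s at 1/5/10/20 Pa); and a distal
recirculation zone appears at the highest pressure drop.

## Known limitations

* **Symmetric branch only.** The steady Picard solver converges to the
  symmetric flow solution; it cannot spontaneously break symmetry the way a
  transient solver at higher Reynolds number can. Asymmetric recirculation
  and the resulting non-uniform mural lysis reported at high pressure drops
  in larger geometries are outside what the scaled, steady computation can
  show; `recirculationMetrics()` reports the top/bottom asymmetry for
  when users run geometries where the instability is physical.
* At scaled Reynolds numbers, flow separation distal to the clot only
  becomes resolvable at the top of the 1–20 Pa range, so the
  recirculation-vs-pressure trend is a weak (non-strict) ordering in the
  shipped tests.
* The clot is initially homogeneous, so lytic fingering from voidage
  heterogeneity cannot occur; clot fragmentation/embolization, platelets,
  red cells, thrombin-driven regrowth and the exposure of fresh binding
  sites by cleavage are all unmodelled.
* The well-mixed tier approaches complete lysis asymptotically (bound
  phases decay in proportion to the remaining fibrin); the spatial kernels
  regularise the endgame by releasing all bound protein in a cell once less
  than 10⁻⁶ n₀ of its fibrin remains, so fully lysed cells end with exactly
  empty bound phases.
* First-order upwind advection smears sharp fronts at implicit CFL > 1;
  breakthrough orderings are robust to this, absolute breakthrough times at
  high pressure drop carry the most numerical diffusion.

## What the tests do and do not show

The synthetic scenarios are the study conditions themselves (there is no
external data): printed-value checks (90 s lysis, 1.65/34.9 µM partition),
literature-range checks (front velocity), closed-form oracles (erfc
diffusion, Poiseuille, Darcy, manufactured divergence), conservation checks
(pooled free + bound inventories to integrator tolerance; discrete mass to
round-off), and phenomenological orderings for the 2D tier, where no
absolute reference numbers exist. Passing them shows the implementation is
faithful to the model and its calibration — not that the model captures any
individual patient's clot, whose fibrin density, permeability and geometry
vary far beyond these defaults.
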