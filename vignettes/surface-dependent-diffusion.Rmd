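---
title: "Surface-dependent diffusion and reactions on triangulated membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-dependent diffusion and reactions on triangulated membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

surfdiff is a single-particle (Brownian dynamics) reaction--diffusion
simulator for molecules confined to membranes, represented as triangulated
surfaces. Its defining feature is that the diffusion coefficient of a
species is looked up per *(species, state, surface)* rather than per species
alone: a named surface (a set of triangular panels) can carry an override
("exemption") on top of the species' default coefficient. Everything derived
from diffusion -- in particular the binding radii used to execute
bimolecular reactions -- is then also computed per surface. This lets one
model spatially heterogeneous membranes, such as a postsynaptic-density
(PSD) microdomain in which AMPA receptors diffuse orders of magnitude more
slowly than in the surrounding extrasynaptic membrane (ESM), without
duplicating molecule types or reactions per region and without erecting
artificial barrier surfaces.

Units are fixed: lengths in µm, times in s, diffusion coefficients in
µm² s⁻¹, bimolecular rates in µm² s⁻¹ (2-D mass action), first-order rates
in s⁻¹, zeroth-order rates in µm⁻² s⁻¹.

### Motion on the mesh

A molecule's position is a panel plus 2-D coordinates in that panel's
tangent frame (origin at the panel's first vertex, first axis along the
first edge -- fixing this convention makes trajectories reproducible
bit-for-bit across runs). Each timestep `dt` the molecule takes a Gaussian
step with per-axis standard deviation `sqrt(2 D dt)`, where `D` is the
coefficient of the surface its panel belongs to **at the start of the
step**; when a step crosses onto another surface the new coefficient takes
effect from the next step. This start-panel rule is the simplest
deterministic discretisation of "adopting the new coefficient in the
process" of crossing; it is an Itô-like scheme with no drift correction,
and its stationary density on a heterogeneous surface is *not* uniform --
molecules accumulate on slow regions in proportion to `1/D` (the Itô
stationary density, modified by a boundary layer of about one rms step at
each surface junction). That accumulation is a deliberate feature (it is
what traps receptors at a slow PSD), not an artefact to be corrected.

Steps are propagated geometrically: straight-line motion within the panel
plane; on exiting through a shared edge the residual displacement is
rotated about that edge into the neighbouring panel's plane (geodesic
unfolding), on exiting through an unmatched (boundary) edge it is reflected
specularly. Unfolding preserves path length exactly, and for coplanar
panels it reduces to straight-line planar motion, which the tests verify
against an independent triangle-wave-folding oracle. Exits that pass
through a vertex are disambiguated deterministically (the edge crossed most
directly wins, lower index on ties). A step entering more panels than
`max_crossings` (default 1000) is an error: it signals a timestep too large
for the mesh resolution, which should be fixed in the configuration rather
than silently truncated.

Per-species confinement (`confine` statement) treats edges between
different surfaces as reflective for that species. The built-in scenarios
use it both to emulate runs in which the two half-planes are independent
reflective surfaces and to pin a kinase to its triangle; the observable
behaviour (the surface label of a confined molecule never changes) is
identical to building two disconnected meshes, and one mechanism covers
both cases.

### Reactions

Zeroth-order sources create `k * area * dt` molecules per surface per step
(Poisson). First-order events fire with probability `1 - exp(-k dt)`.
Bimolecular reactions use the binding-radius method: after diffusion, any
reactant pair closer (in 3-D) than `sigma_b` reacts; candidate pairs are
processed in ascending separation and each molecule reacts at most once per
step. For a pair whose molecules sit on surfaces i and j, `sigma_b` is
calibrated from the mutual coefficient `D_i(reactant 1) + D_j(reactant 2)`,
so a slow surface gets a larger capture radius for the same macroscopic
rate.

The calibration works in reduced units (length unit = per-axis rms step
`s = sqrt(2 D_mutual dt)`). The radial density of the pair separation
evolves under the Rice-distribution transition kernel of a 2-D Gaussian
step; all probability inside `sigma_b` is absorbed each step and the far
field is held at bulk density beyond a screening distance (`far_field`,
default 10 rms steps beyond contact). The steady state of this
propagate/absorb/reset map is an affine fixed point and is solved directly
as a linear system on a radial grid windowed around the absorbing boundary
(500 cells spanning 8 rms steps below to `far_field + 6` above contact;
sub-cell absorbing radii are handled by partial-cell absorption, and the
Bessel `I0` factor switches to its asymptotic series for large arguments).
Root finding on the absorbed flux then yields `sigma_b`. Two caveats are
inherent to two dimensions and documented rather than hidden:

* the steady 2-D rate depends logarithmically on where the bulk is
  maintained, so "the" macroscopic rate is only defined together with a
  screening distance; the Monte-Carlo check in the tests uses a periodic
  box whose area matches the calibration's screening disc and recovers the
  requested rate to within ~10%;
* a rate far above the diffusion-limited encounter rate (e.g. binding to
  scaffolds on a nearly frozen surface, `k/(2D) >> 1`) would demand an
  unbounded capture radius. `binding_radius_from_rate()` reports the
  achievable maximum as an error; the reaction-table layer instead caps
  `sigma_b` at 50 rms steps with a warning, leaving the reaction
  diffusion-limited -- which is precisely the encounter-starved regime the
  receptor-trapping scenario is meant to exhibit.

For reversible reactions, the products of a dissociation are placed at the
unbinding radius `sigma_u`, calibrated with the same radial machinery so
that the probability of geminate recombination equals `pgem` (default
0.2). A 2-D random walk is recurrent, so "escape" is defined as reaching 12
rms steps beyond the binding radius before recombining; the brute-force
pair simulation in the tests uses the same definition and matches to
within Monte-Carlo error.

### The step loop and determinism

Each step executes creations, first-order events, diffusion (ascending
molecule id), bimolecular events, then observers; molecules created earlier
in a step do diffuse in that step. All randomness is drawn from R's RNG in
this fixed order, so equal (configuration, seed) pairs give byte-identical
output files, and a run whose `surface_difc` overrides are numerically
equal to the defaults is byte-identical to the run without overrides.
Simulation time is accumulated by step count, never by adding floats.

## Scenarios and the choices behind them

The three built-in generators produce the study conditions programmatically.
Where the underlying publications state values (copy numbers, the
hundredfold diffusion contrast, D_ESM = 0.45 µm² s⁻¹, 66 receptors, 132
scaffolds), those are the defaults. Values they do not state are fixed here
once, with the reasoning below, and exposed as parameters.

**Two-triangle plane** (`scenario_two_triangle()`): a 1 × 1 µm square split
along its diagonal into `fast` and `slow` triangles. Defaults D_fast = 0.1,
D_slow = 0.001 µm² s⁻¹ -- a typical membrane-protein mobility and a
hundredfold contrast; at these values a 100 s trajectory explores both
triangles, and the crossover between free and confined behaviour falls
inside the observable lag window, which is what makes the mean square
displacement (MSD) visibly anomalous. `scenario_free_plane()` provides the
homogeneous control (default 50 × 50 µm so a 10 s run at D = 0.45 never
feels the walls).

**Phosphorylation** (`scenario_pip()`): PIP2 + PI3K → PIP3 + PI3K on the
two-triangle plane, 3 kinases and 500 PIP2 per triangle, kinase confined.
The literature rate for this reaction is not printed in a usable form, so
`k` is a parameter; its default 0.006 µm² s⁻¹ makes the per-substrate
conversion rate `k · n_kinase / area ≈ 0.036 s⁻¹`, i.e. roughly half the
fast triangle's substrate converts within 20 s -- fast enough to resolve at
desk scale, slow enough that the fast/slow contrast is not saturated. The
assertions on this scenario are the qualitative orderings (fast surface
leads without crossing; with crossing the slow surface overtakes its own
no-crossing yield), never k-specific values.

**Spine head** (`scenario_spine()`): a triangulated sphere of radius
0.5 µm (a typical spine head) with a 20° neck opening whose rim reflects,
and a polar `psd` cap sized to ~10% of the head area (measured share with
the default 12 × 16 triangulation: 0.119). 66 AMPAR start uniformly; with
scaffolds, 132 immobile scaffold molecules sit uniformly in the PSD and
AMPAR binds them reversibly. k_on and k_off are again exposed parameters:
k_on = 0.01 µm² s⁻¹ is chosen so that at uniform D = 0.45 a receptor
visiting the PSD has clearly less than unit probability of binding per
visit (per-visit dwell ~0.05 s times encounter rate `k_on · scaffold
density ≈ 4.4 s⁻¹`), so that slowing the PSD measurably *helps* trapping
before extreme slowness starves it; k_off = 0.001 s⁻¹ makes binding
effectively long-lived on the simulated horizon. The bound complex is
immobile, as scaffold-anchored receptors are on these time scales.

## What the tests do and do not show

The test suite validates, at fixed seeds: seed determinism and
override-equivalence byte-for-byte; the free-diffusion law (MSD slope
within 5% of 4D for 1000 particles); subdiffusion (log-log MSD slope
< 0.95) on the heterogeneous plane; steady-state slow:fast occupancy
against an independent 1-D two-zone random-walk oracle with the same step
rule, timestep, zone size and burn-in window (within 10%; the stationary
ratio of the discretisation is near `D_fast/D_slow`, approached through a
one-rms-step interface layer, so matched scales matter); first-order survival
within 3 Poisson standard deviations of e⁻¹; Monte-Carlo recovery of a
calibrated bimolecular rate within 10%; the kinase-scenario orderings over
5 seeds; monotone PSD enrichment across the tenfold D_PSD sweep (12 seeds,
180 s horizon, averaging the last 60 s) and the non-monotone
time-to-90%-bound with scaffolds (5 seeds, 120 s horizon, censored at the
horizon); and the geometric identities (path-length conservation and the
coplanar reduction, 10⁴ random steps at 10⁻⁹ relative tolerance).

Problem sizes are deliberately desk-scale: hundreds of seconds of simulated
time and tens to thousands of molecules, chosen so that the expected
orderings exceed seed-to-seed variability several-fold.
The synthetic scenarios emulate heterogeneous diffusion,
confinement and scaffold binding; they do not emulate molecular crowding,
anisotropic or curvature-dependent diffusion, receptor exocytosis, or the
irregular geometry of real spines, so passing tests demonstrate the
simulator's internal consistency and the mechanisms above -- not agreement
with any particular experimental trace.

Two further numerical notes. The stationary occupancy ratio of the
discretised walk is a property of the scheme (≈ `sqrt(D_fast/D_slow)`),
approached at the boundary-layer resolution of one rms step; tolerances in
the tests account for this. And trapping by slow diffusion concentrates
newly arrived molecules near the subarea's rim at early times (they must
random-walk inward at the slow coefficient), which the tests verify as an
elevated mean polar angle relative to a uniform-in-cap placement; trapping
by explicit scaffold binding instead inherits the scaffolds' uniform
placement. The two mechanisms produce similar saturating enrichment time
courses but different spatial distributions inside the domain.

## Reproducing the headline numbers

`scripts/acceptance.R` (run from the repository root as
`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`)
regenerates every scenario from scratch at the scales above and writes the
fitted MSD slope and exponents, the occupancy ratio and its 1-D oracle, the
first-order survival fraction, the Monte-Carlo rate recovery, the kinase
orderings, the trapping-trend summaries and the worst-case path-length
error as a JSON file.
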