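---
title: "Adaptive micro-FE loading of healing bone: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive micro-FE loading of healing bone: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During bone-defect healing the geometry of the callus changes week by week.
A fixed compressive force applied to a healing femur therefore delivers a
*different* tissue-scale strain stimulus at every time point and to every
animal: a freshly bridged, fragile callus is strained far more by 10 N than
a consolidated one. If the experimental question is about the effect of a
defined mechanical stimulus, this drift is a confounder. The remedy
implemented here is real-time finite-element (rtFE) adaptive loading: at
each imaging session, convert the current mineral-density image into a
voxel-level mechanical model, compute the strain distribution per unit
force, and choose the force whose predicted strain distribution best matches
a fixed reference — then screen that force against refracture risk before it
is ever applied.

`rtfe` implements that whole chain offline: a synthetic phantom generator
standing in for in vivo micro-CT, image preprocessing, the density-to-
stiffness material map, a voxel micro-FE solver, the distribution-matching
and fracture-guard adaptation layer, and cohort-level reporting.

## Image preprocessing

Volumes are 3-D arrays of volumetric bone mineral density (mg HA/cm³) on an
isotropic grid; the third axis is the axial (loading) direction. The
standard pipeline is:

1. crop to the region of interest (the full-resolution protocol uses
   300 × 300 × 210 voxels at 10.5 µm between the fixator screws);
2. after longitudinal registration, trim 15 axial slices from each end
   (registration rotates/translates the volume and leaves partially empty
   end slices), e.g. 210 → 180 slices;
3. smooth with a truncated Gaussian, σ = 1.2 voxels, support = 1.

"Support" is interpreted as the integer half-width of the kernel: a
3 × 3 × 3 separable kernel holding the Gaussian density at offsets −1, 0, 1
per axis, renormalized to unit sum. σ is in voxel units, the convention of
this imaging pipeline family. Boundaries are mirror-padded so volume faces
are not darkened; a constant volume passes through unchanged and interior
mass is conserved. Registration itself is *not* implemented — the package
consumes pre-registered volumes and records a registration flag in
metadata. Indexing is 1-based throughout (R convention); shapes are
reported as (x, y, z).

## Material model

Mineralized tissue is mapped to isotropic linear elasticity through a
14-level ladder: densities from 395 to 720 mg HA/cm³ in 25 mg HA/cm³ steps
map linearly to Young's moduli 4.045 to 12.170 GPa. The printed endpoints
imply a step of (12.170 − 4.045)/13 = 0.625 GPa exactly, and the endpoints
are taken as authoritative. Quantization uses the floor rule (a density in
[395, 420) sits on level 0); densities at or above 720 clamp to the top
level. Both choices are configurable (`quantization`, and the ladder
parameters themselves) because the rounding convention is not dictated by
the density grid alone.

Densities below 395 are soft tissue at 0.003 GPa. Soft-tissue voxels are
*kept in the mesh* — they carry (very little) load and, importantly, they
sit on the loaded face of the mesh wherever the medullary canal meets it.
For that reason the marrow cavity at the top slice is capped: soft voxels
inside the transverse convex hull of that slice's bone are converted to a
20 GPa plate, preventing the prescribed displacement from being absorbed by
near-zero-stiffness tissue at the boundary. Cap voxels are excluded from
every analysis mask, as is all soft tissue: the "mechanical environment" is
the strain multiset over bone voxels only. Poisson's ratio is a single
global 0.3 (standard in this micro-FE lineage; configurable). Internal
units are mm / MPa / N, so reaction forces come out in newtons; moduli are
GPa at the interface.

## Voxel micro-FE

Every voxel is one trilinear 8-node hexahedral element (2 × 2 × 2 Gauss
quadrature). Because all elements share shape and orientation, one unit-
modulus reference stiffness is scaled per element, and the global operator
is applied matrix-free (no assembled matrix), keeping the 300³-scale memory
footprint linear in the grid. The system is solved with Jacobi-
preconditioned conjugate gradients, relative-residual tolerance 10⁻⁶ by
default and an iteration cap of 10·√(n_dof) (both overridable). The
initial iterate is the linear axial compression ramp, which is the exact
solution for a homogeneous column and a good start for anything resembling
one.

Boundary conditions follow the compression protocol: bottom-slice nodes
fully fixed, top-slice nodes displaced axially by 1% of the domain length
(δ = 0.01) with transverse components free (a `top = "fixed"` variant
exists; the scaling step uses only axial reactions, so either choice is
self-consistent). A `roller` bottom mode (axial fix plus minimal rigid-body
pins) exists purely for validation: under roller support a homogeneous
block is in uniform uniaxial stress, so every element must show an
effective strain of exactly δ (10,000 µε) and the resultant force must be
E·δ·A — a closed form the test suite checks to below 0.1% on grids up to
32³, alongside agreement of the iterative solve with a dense direct solve
to 10⁻⁸ on tiny grids.

Per element, the strain energy density U = ½ uᵀKu / V is evaluated from
the element displacement vector (one value per voxel), and the effective
strain is ε_eff = √(2U/E) — the scalar strain measure standard in this
literature. The resultant force F_resultant is the sum of axial nodal
reactions on the top surface; top and bottom reaction sums balance at
convergence.

Before solving, the mesh is checked for a bone/cap load path connecting the
faces (6-connected flood fill); a mechanically disconnected problem is
still solvable — soft tissue carries the load — but is flagged with a
warning, since its strain field means something quite different.

## Strain scaling and load matching

Linearity makes one solve serve every force: strains at an applied force F
are the simulated strains times F / F_resultant. The adaptation layer works
entirely on this rescaling:

* `make_target()` rescales a reference sample (ideally a well-healed
  subject's distribution) to a median of 700 µε. The true reference
  distribution of a given study is not shipped anywhere, so the package
  provides `default_target()`, a synthetic log-normal stand-in
  (right-skewed like real effective-strain distributions, sdlog 0.5); the
  target is otherwise a required input.
* `match_load()` minimizes the two-sample Kolmogorov–Smirnov statistic
  between the rescaled distribution and the target over the applied force,
  with a one-dimensional Nelder–Mead search. For finite samples D is
  piecewise constant in the scale factor, so convergence is declared on
  tolerances — 0.01 N on the simplex width and 10⁻⁴ on the D spread, 200
  evaluation cap — rather than on any gradient criterion. The search starts
  at the median-matching force F₀ = F·median(target)/median(dist), simplex
  {F₀, 1.05·F₀}. Force is continuous during matching; an optional
  `load_grid` snaps the result to an actuator menu, and
  `enumerate_loads()` exposes the full plot-and-select table (ranked by D,
  ties to the smaller force).
* `fracture_guard()` screens the matched force: count bone voxels at or
  above 10,000 µε; while the count is at or above 50, reduce the force by
  2 N and recount. Counting is done by exact linear rescaling — for a
  linear model this equals re-solving, so no FE call is needed inside the
  loop. Two readings in the protocol's wording differ at exactly 50
  voxels; the conservative one (downscale at count ≥ 50) is used, and the
  threshold comparison is ≥ 10,000 µε. If no positive force reachable by
  2 N steps satisfies the criterion the plan is flagged "do not load" —
  never silently clamped. The size of the largest 26-connected
  over-threshold cluster is reported (`overstrain_cluster_size()`) because
  adjacency in thin struts is the actual refracture concern, but it does
  not alter the stopping rule, which is defined purely by count.

`rtfe_session()` chains preprocess → material → solve → mask → match →
guard and reports per-stage timings, the plan, and the pre- and post-guard
distributions.

## The phantom generator

No imaging data ships with the package, so the generator produces the study
conditions synthetically: a hollow cylindrical cortex (700 mg HA/cm³ wall)
along the axial axis, a transverse osteotomy gap, bridging callus, soft
background (100 mg HA/cm³), and additive Gaussian density noise (SD
15 mg HA/cm³, truncated at zero — the simplest model consistent with
filtered micro-CT appearance). Callus has three ingredients:

* discrete *struts* at deterministic angular positions with seeded jitter
  (reproducible yet varied cohorts), anchored two slices into each
  fragment;
* a porous *bridging fill* over the cortical footprint inside the gap,
  selected by a seeded per-column lottery so that a larger fill fraction
  strictly grows the fill;
* an optional periosteal *collar* around the gap, adding load-bearing
  area the way external callus does.

The default grid is 48 × 48 × 60. The voxel size scales as
0.0105 × 300/shape[1] mm so that every phantom spans the same 3.15 mm
femoral segment: a desk-scale phantom is the full segment imaged coarsely,
not a miniature. This keeps resultant forces, matched loads and the 2 N
actuator step on the newton scale of the in vivo protocol (a miniature at
native resolution would see ~0.1 N forces, for which a 2 N decrement is
meaningless). At shape 300 the native 10.5 µm spacing is recovered. The
defect geometry itself (radius 14 voxels, wall 4, gap 8 slices) is a free
design choice — the protocol publishes no quantitative defect geometry —
sized to a mouse femur's ~1.9 mm outer diameter.

Healing series share one seed across weeks, so the noise field and fill
lottery are identical and only geometry changes: *formation-like* series
(loaded-group analogue) thicken struts, raise the fill fraction and callus
density and grow the collar, making bone voxel count non-decreasing by
construction; *resorption-like* series (control analogue) thin the cortex
and struts and lose fill, making it non-increasing. Weekly rates (strut
+0.5 voxel, fill +0.15, density +30 mg HA/cm³, collar +0.75 voxel;
thinning 0.4 voxel) were chosen once to move the per-unit-force median
strain by tens of percent over five weeks, the magnitude of change visible
in longitudinal healing data.

`make_overloaded_strut_phantom()` builds the refracture scenario: a single
thin (radius 2.2), weakly mineralized (420 mg HA/cm³) strut bridging a
widened gap. Its contract — more than 50 bone voxels at or above 10,000 µε
at the documented reference load (half the phantom's own resultant force),
and none at a tenth of it — is verified by an embedded solve at generation
time, and generation fails loudly if the contract cannot be met.

What the phantoms deliberately do not emulate: trabecular
microarchitecture, beam hardening and partial-volume physics, soft-tissue
contrast, or the registration step itself. Passing tests on phantoms
therefore validate the *pipeline mechanics* (preprocessing contracts, the
solver, scaling, matching, guarding, reporting) — they do not certify
biological realism of any particular strain value.

## Cohort reporting

`strain_histogram()` uses the fixed reporting grid (250 half-open bins over
0–15,000 µε, width 60); values at or above the upper edge go to an explicit
overflow bucket rather than being dropped, so counts are always conserved.
Per-animal summaries are medians; group cells report mean ± sample SD
(n − 1 denominator; a single-animal cell reports the mean with SD marked
undefined). `compare_scenarios()` evaluates the constant-force (default
10 N) and adaptive scenarios on the *identical solves* — the constant
scenario is the same distribution rescaled to a fixed force — and reports
per-(group, week) mean ± SD under both, their SD ratio, and per-animal
recommended-load trajectories. Group-vs-group distributional comparisons
reuse the KS statistic.

The packaged study-condition cohort (`example_cohort()`) is five animals —
three formation-like, two resorption-like — with seeded anatomical jitter
(cortex radius 12.5–15.5 voxels, wall 3.5–5.5, gap 7–10 slices, callus
density 440–560, 2–4 struts, mode-dependent bridging state), five weekly
time points each. At the desk-scale grid the 25 solves complete in roughly
ten minutes on one CPU; this is the problem size used by the test suite's
cohort check. On it, adaptive loading holds per-animal medians near the
700 µε target while the constant-force scenario drifts with geometry, so
the across-animal SD of medians is smaller under adaptation at every week,
and recommended loads fall over time for resorption-like animals and rise
for formation-like ones — the qualitative signature of the in vivo
approach.

## Numerical choices and degenerate inputs

* CG tolerance 10⁻⁶ (relative residual) suffices for strain distributions;
  validation tests tighten it to 10⁻⁸–10⁻¹¹ where they compare against
  closed forms or dense solves.
* A zero prescribed displacement short-circuits to the zero solution.
* Isolated nodes (no attached stiffness, impossible with soft tissue
  retained but guarded anyway) get unit diagonal entries.
* `match_load()` on a degenerate single-valued distribution converges to
  the shape-mismatch floor of D and reports it honestly; the convergence
  flag and evaluation count are in the plan.
* Histogram bin edges are left-closed/right-open; a value exactly at 60 µε
  lands in bin 2.
* KS ties are handled by evaluating both ECDFs on the pooled support (no
  continuity assumption).
* `make_target()` is idempotent and rejects non-positive medians;
  `fracture_guard()` never returns a clamped force — failure is explicit.

## Known limitations

* Linear elasticity only: no contact, damage, or geometric nonlinearity;
  the risk metric is a conservative count, not a validated failure
  assessment.
* The solver is single-threaded; full 300 × 300 × 210 problems are
  supported in memory but are supercomputer-scale in time for routine use.
* The fracture guard's 2 N step and 50-voxel limit are protocol constants,
  not biology; both are parameters of `guard_params()`.
* Phantom cohorts share an idealized cylindrical anatomy; conclusions
  about method behaviour on real, irregular calluses require real images.
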