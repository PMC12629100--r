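---
title: "Planning no-touch ablations with a passive steerable needle: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning no-touch ablations with a passive steerable needle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arcplan)
```

This vignette explains what `arcplan` computes, the assumptions behind each
model layer, the parameters that matter and how their defaults were chosen,
and what the synthetic phantoms do and do not establish about real data.

## Scene model

A planning scene is an integer label grid (`background`, `skin` = whole soft
tissue, `liver`, `tumor`, `margin`, `vessel`, `bone`, `other_risky`) plus
world geometry: a voxel size per axis, the world position of the first voxel
center, the operating-table plane, and the patient's posterior direction.
All world coordinates are millimetres; voxel indices address voxel centers,
and masks are plain label-equality tests. Surfaces (skin and obstacle
boundaries) are represented as dense sampled point clouds rather than
triangle meshes: every exposed boundary voxel face is covered with a sub-grid
of points at most 1 mm apart, which is exactly what the distance queries
need. Distance queries are exact over these samples — a two-phase search
(strided subsample for an upper bound, then an axis-aligned-box prune)
keeps them fast without approximation.

The 10 mm safety margin is built by labeling every voxel whose center lies
within the margin distance (measured in world mm, so anisotropic voxels are
handled correctly) of a tumor voxel center. The margin only overwrites
liver (and optionally background) labels — never vessels or bones — and is
clipped to the liver by default, with the clipped fraction recorded on the
scene. Clipping is the conservative choice: tissue outside the organ cannot
be part of an intrahepatic ablation target, and the recorded fraction flags
scenes where the shell is incomplete.

Bones play two distinct roles: they are always *hard obstacles* (the needle
may never cross them), but they are *excluded* from the reported minimum
clearance and from the distance penalty by default
(`distance_includes_bones = FALSE`), since ribs routinely sit within a few
millimetres of any intercostal path and would otherwise dominate the metric.

## Needle model

The needle is a rigid shaft with an articulated tip: five flexure joints,
each bending 6°, spaced 3.5 mm apart, with a 5 mm beveled distal section
(2.8 mm shaft diameter). The planner uses the simplification that all joints
are released at once at the flexion point, at maximal bend — giving a fixed,
predictable arc. Per-joint release schedules are out of scope.

Two readings of the joint layout are possible; `arcplan` places the *first
joint at the flexion point*, followed by four 3.5 mm gaps and the 5 mm
distal section, so the tip arc is 19 mm long with defaults. This is a
configuration choice (`arc_needle_spec()`), not a claim about the hardware.
The bending-plane reference (the direction meaning "plane angle zero") is
the unit vector orthogonal to the shaft closest to the scene's +x axis —
any fixed convention works, determinism is what matters.

A plan's trajectories are: one straight segment (entry point, aimed at the
tumor centroid, down to the flexion depth), then `N` curved branches at
bending-plane angles `shift + 2πk/N`. The ablation applicator (catheter) is
extended beyond each branch tip along its final tangent; the extension
defaults to the distance from the tip to the tumor-centroid depth plane,
clamped to [0, 20] mm and shortened in 1 mm steps while its tip would leave
the liver. This deterministic rule keeps the search space at the four
planning variables rather than adding per-branch depths. For the
`prox`/`dist`/`both` variants, extra in-tumor ablation centers are placed on
the straight axis half a long semi-axis past the tumor entry / before the
tumor exit, clamped onto tumor voxels; only the catheter (never the needle)
crosses the tumor, so the no-touch rule is preserved by construction.

## Ablation simulation and metrics

Each ablation is a prolate ellipsoid of revolution about its catheter axis,
rasterized by testing voxel centers against the ellipsoid inequality.
Defaults — semi-axes 20 × 15 × 15 mm, center offset −a/3 behind the tip —
are geometric placeholders representative of a 100 W / 10 min microwave
protocol; they are metadata, not physics, and every report flags them as
overridable. Vessel heat sinks, perfusion and tissue heterogeneity are
deliberately absent: the contribution under test is geometric coverage
planning, and any better ablation-shape model slots in via
`ablation_params()`.

Metrics: `M` (fraction of tumor∪margin covered), `tumor_coverage`, `H`
(fraction of ablated volume outside tumor∪margin), `efficiency = 1 − H`,
`d_min` (minimum clearance over all needle polylines and catheter segments,
needle radius subtracted, bones excluded by default), and the penalty
`D = max((5 − d)/5, 0)`. An empty ablation mask is defined as `M = 0,
H = 0` so the score is total. The score's `N` counts *peritumoral*
ablations only — the proximal/distal additions are a per-run variant, not a
searched variable, and reported ablation counts include them.

Infeasible plans are never scored: feasibility is handled by the swarm's
update scenarios rather than by a penalty term, which keeps the score
landscape unpolluted and matches the constraint-handling design.

## The constrained swarm (PSAM)

The search space has four dimensions: entry index (over the preprocessed
admissible list, ordered by polar angle then azimuth around the tumor so
that neighboring indices are spatially adjacent), ablation count `N ∈ [1,8]`,
flexion depth, and the first bending-plane shift. The swarm moves through a
continuous relaxation; integrality enters only at decoding (round and
clamp). The shift is stored *normalized* in [0, 1] and scaled by `2π/N` at
decode time, so its bounds never move when `N` changes mid-flight — a
requirement for fixed per-dimension bouncing bounds.

Flexion-depth bounds are scene-derived: 10 mm past the skin up to the
largest entry-to-margin distance minus a 2 mm tip clearance, which
guarantees the flexion point precedes the target; configurations whose
depth exceeds *their own* entry's margin distance are flagged infeasible
rather than clamped.

Per iteration, each particle is evaluated and classified:

1. **feasible** — classic update
   `v ← w·v + c1·μ1·(pbest − x) + c2·μ2·(gbest − x)`;
2. **infeasible, memory empty** — the particle is reinitialized uniformly
   at random (velocity zeroed, personal best cleared: a full restart);
3. **infeasible, memory nonempty** — an additional term
   `c3·μ3·(rhistory − x)` pulls toward a uniformly drawn remembered
   feasible position.

Undefined personal/global bests default to the particle's current position,
canceling their terms. The memory is a 256-entry ring buffer of every newly
encountered feasible personal/global best (positions and scores — a
harmless superset of what recovery needs). The global best updates
synchronously at the end of each iteration; the stagnation counter resets
only on *strict* improvement and the run stops after 50 stagnant iterations.
A `max_iter` cap (default 400) bounds runs on continuous objectives where
strict improvements never cease; on the voxelized planning objective, score
plateaus make the stagnation rule bite naturally (runs on the shipped
phantoms converge in roughly 60–70 iterations). The uniforms `μ` are drawn
per dimension (vector-PSO convention; `shared_mu` switches to scalar
draws). Positions leaving a bound are reflected back inside
(`x' = 2·min − x` / `x' = 2·max − x`, repeated until interior), preserving
exploratory velocity near limits; velocities are left untouched by the
reflection.

Initialization is uniform within bounds with zero velocities (zero initial
velocity avoids immediate boundary bouncing). Every source of randomness
runs under a local RNG seeded from the `seed` argument, so runs are
bit-reproducible and never disturb the caller's RNG state.

## Monte-Carlo baseline

`run_monte_carlo()` draws 1000 configurations uniformly (integer dimensions
uniform over their integer range; draws are sequential so a larger budget
nests a smaller one under the same seed), evaluates them with the identical
feasibility check and score, and returns the best feasible draw. Infeasible
draws consume budget — the sampler is "semi-exhaustive", not
rejection-resampled. When a single theoretical ablation volume could cover
the whole target, the sampled `N` is capped at 4; "could cover" is
implemented orientation-free as *tumor∪margin fits inside the ellipsoid's
inscribed sphere centered at the tumor centroid*, a deterministic sufficient
condition (configurable off).

## Entry-point preprocessing

Skin surface samples are filtered by: obstacle-free straight corridor to the
tumor centroid, truncated at the margin surface and thickened by the needle
radius (the thickening probes four lateral offsets at ±r, a deliberate
discrete approximation of a swept cylinder); non-posterior position;
no table-plane crossing; and liver incidence angle ≤ 30°, measured against
the liver-surface inward normal at the ray's liver entry (the organ-relative
reading, not the skin normal). Normals are estimated from the local mask
neighborhood — deterministic and mesh-free. The admissibility ray stops at
the margin so the test itself never violates the no-touch rule.

## Synthetic phantoms

`generate_phantom()` rasterizes geometric primitives — superellipsoid body,
ellipsoidal liver, ellipsoidal tumor (the roster spans the 75–16,900 mm³
clinical volume range), capsule vessels in the posterior liver, rib-like
bone capsules, optional bone shells with angular windows — with precedence
bone > vessel > tumor > margin > liver > skin. The roster
(`make_test_suite_scenes()`): **easy** (a 3 mm tumor a single default
ablation can cover, clear anterior window), **narrow** (a bone-shell window
plus a vessel crossing the only corridor 2 mm off-axis, so every feasible
plan has `d_min < 5` mm and `D > 0` — the offsets were chosen analytically
from the window aperture and vessel radius), **large** (~16,900 mm³ tumor,
uncoverable by one ablation), and **blocked** (complete bone shell; the
planner must fail with a clean "no admissible entry point").

Phantoms are geometric, not anatomically deformed: organs are convex-ish
primitives, vessels are straight capsules, and there is no CT intensity or
segmentation noise. Passing tests therefore establish the *algorithms* —
geometry, constraint handling, optimization — not clinical performance on
patient segmentations, where irregular organ shapes, segmentation error and
real ablation physics all enter.

## Numerical choices and problem sizes

* Trajectories and obstacle surfaces are sampled at ≤ 1 mm; distance values
  consequently carry a ~1 mm sampling tolerance, which the tests assert.
* Rasterization tests voxel centers; volumes of primitives match analytic
  values within 3–5 % at 1–1.5 mm voxels (asserted on spheres and
  ellipsoids).
* Plan evaluations are memoized on the decoded configuration (evaluation is
  deterministic, so this is exact); the discretized-space oracle tests
  (3 entries × N ∈ 1..4 × 5 depths × 4 shifts = 240 configurations) share
  one cache across exhaustive enumeration and all planner runs.
* The shipped test scenes run at 2 mm voxels (≈ 73³ grids) and the default
  phantom at 1.5 mm — sizes chosen so a full planner run takes tens of
  seconds on a laptop-class single core while voxelization error stays
  within the asserted bounds.
* Degenerate inputs: an empty tumor errors (`"empty tumor"`); a scene with
  no admissible entry errors (`"no admissible entry point"`) and batch runs
  record the failure per row; a search with no feasible configuration
  returns a structured `"no feasible plan"` result with diagnostics rather
  than an error.

## Known limitations

Fixed maximal curvature (all joints released at once) can make narrow
tumors unreachable without excess collateral damage; per-joint release is
the natural extension. The catheter-extension rule is a deterministic
heuristic, not an optimized variable. Ablation volumes are unvalidated
placeholders. The table is a plane, not a mesh; intercostal anatomy is not
modeled. The optimizer returns a single scalarized optimum, not a Pareto
front.
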