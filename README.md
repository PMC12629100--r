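# arcplan

Automatic planning of percutaneous **no-touch thermal ablation** with a
passive steerable needle.

## The problem

Thermal ablation of liver tumors with the *no-touch* technique surrounds the
tumor with ablation volumes whose applicators never penetrate it, reducing
seeding and recurrence risk. With conventional rigid needles this requires
several separate skin insertions. A passive steerable needle with
controllable stiffness (a straight hollow shaft plus an articulated beveled
tip whose flexure joints can be locked or unlocked) can instead reach several
peritumoral positions from a *single* insertion: the needle is advanced
straight to a *flexion point*, the joints are released so the tip bends along
a predictable arc, and between ablations the needle is withdrawn to the
flexion point and rotated to a new bending plane. Planning such interventions
by hand is hard — the search space couples the skin entry point, the number
of ablations, the flexion depth, and the rotation of the bending planes.

`arcplan` implements that planner end to end, testable without any patient
data through a synthetic anatomical phantom generator.

## The model

A candidate plan is scored with

```
Score = M − w1·N − w2·H − w3·D ,       D = max((s − d)/s, 0)
```

where `M` is the fraction of the tumor-plus-margin volume (10 mm safety
margin) covered by the simulated ablations, `N` the number of peritumoral
ablations (1–8), `H` the fraction of the ablated volume that is healthy
tissue, and `D` a penalty that grows linearly as the minimum
needle-to-obstacle clearance `d` drops below the safety distance `s = 5` mm.
Default weights are `w1 = 0.05`, `w2 = 0.2`, `w3 = 0.5`.

Hard constraints — no needle/obstacle intersection, unlocked joints and the
catheter inside the liver, no needle–tumor contact, anterior entries only,
liver incidence ≤ 30° — are handled by **PSAM**, a constrained particle
swarm (inertia `w = 0.724`, coefficients `c1 = c2 = c3 = 1.468`, 8
particles, stop after 50 stagnant iterations) that keeps a memory of
feasible solutions: feasible particles follow the classic inertia +
cognitive + social update, infeasible particles are pulled toward a random
remembered feasible position (or randomly restarted while the memory is
empty), and out-of-range coordinates are reflected back inside by *bouncing
bounds*. A seeded Monte-Carlo sampler over the same space serves as the
baseline.

Ablation volumes are geometric placeholders: prolate ellipsoids
(20 × 15 × 15 mm semi-axes by default, standing in for a 100 W / 10 min
microwave ablation) rasterized against the label grid. No bioheat physics is
simulated; override `ablation_params()` for anything clinical.

## Worked example

```r
library(arcplan)

scene   <- make_test_suite_scenes(voxel_mm = 2, which = "easy")[[1]]
entries <- generate_entry_candidates(scene)
res     <- run_psam(scene, entries, variant = "both", seed = 42)
print(res$best_metrics)
cat(sprintf("Score = %.3f\n", res$best_score))
```

```
anatomy_scene: 73 x 73 x 73 voxels at 2 x 2 x 2 mm
entry_point_set: 5870 admissible skin entry points (<= 30 deg)
status: ok after 67 iterations
plan metrics: M=1.000 tumor=1.000 H=0.676 eff=0.324 N=1 (total 3) d_min=20.68 mm D=0.000
Score = 0.815
```

Reading: the optimizer found a single insertion with one peritumoral curved
branch plus the proximal and distal in-tumor ablations of the `both`
variant (3 ablations total), covering 100 % of the tumor and its margin
(`M = 1`), staying 20.7 mm clear of every vessel (`D = 0`); 67.6 % of the
ablated volume is healthy tissue, reflecting how much larger the default
ablation ellipsoid is than this small (3 mm radius) tumor. The score
`1 − 0.05·1 − 0.2·0.676 = 0.815`.

Other entry points: `run_monte_carlo()` (baseline), `run_experiment()`
(batch comparison table), `build_margin()`, `min_surface_distance()`,
`check_feasibility()`, `export_plan_json()`. A thin command-line wrapper
with `phantom` / `preprocess` / `plan` / `mc` / `score` / `report`
subcommands lives at `inst/cli/arcplan.R`.

## Scope

Geometry only: no image registration or segmentation (label volumes are
consumed as given, NIfTI/ASCII-NRRD), no needle–tissue mechanics, no
thermal simulation, and single-scalar optimization (no Pareto front). See
`vignettes/arcplan-methods.Rmd` for the modeling choices and their
rationale.
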