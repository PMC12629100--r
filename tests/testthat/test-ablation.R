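# Ablation rasterization and coverage metrics.

# minimal hand-built trajectory set carrying only what the rasterizer and
# metrics need
fake_ts <- function(tips, axes, n_peritumoral = nrow(tips)) {
  structure(list(
    entry = c(0, -60, 0), shaft_dir = c(0, 1, 0),
    flexion_point = c(0, -20, 0),
    straight = resample_polyline(rbind(c(0, -60, 0), c(0, -20, 0)), 1),
    branches = list(),
    catheter_tips = tips, catheter_axes = axes,
    tip_kind = rep("branch", nrow(tips)),
    config = list(n_ablations = n_peritumoral),
    needle_spec = arc_needle_spec(),
    violations = character(0)
  ), class = "trajectory_set")
}

test_that("rasterized ellipsoid volume matches the analytic value", {
  scene <- bare_sphere_scene(tumor_radius = 6, voxel = 1, margin = 5,
                             half_extent = 30)
  params <- ablation_params(a_long_mm = 20, b_trans_mm = 15,
                            center_offset_mm = 0)
  ts <- fake_ts(rbind(c(0, 0, 0)), rbind(c(0, 1, 0)))
  mask <- rasterize_ablations(ts, params, scene)
  analytic <- 4 / 3 * pi * 20 * 15 * 15
  expect_lt(abs(sum(mask) * prod(scene$voxel_size) - analytic) / analytic,
            0.03)
})

test_that("empty tip set and coincident tips behave as set unions", {
  scene <- bare_sphere_scene(tumor_radius = 6, voxel = 1, margin = 5,
                             half_extent = 30)
  params <- ablation_params()
  empty <- fake_ts(matrix(0, 0, 3), matrix(0, 0, 3), n_peritumoral = 0)
  m0 <- rasterize_ablations(empty, params, scene)
  expect_false(any(m0))

  one <- fake_ts(rbind(c(0, 0, 0)), rbind(c(0, 1, 0)))
  two <- fake_ts(rbind(c(0, 0, 0), c(0, 0, 0)),
                 rbind(c(0, 1, 0), c(0, 1, 0)))
  expect_identical(rasterize_ablations(one, params, scene),
                   rasterize_ablations(two, params, scene))
})

test_that("coverage metrics match a brute-force voxel-count oracle", {
  scene <- bare_sphere_scene(tumor_radius = 6, voxel = 1, margin = 5,
                             half_extent = 30)
  params <- ablation_params(a_long_mm = 10, b_trans_mm = 8,
                            center_offset_mm = 0)
  tip <- c(0, 4, 0)    # offset so the ellipsoid covers part of tumor+margin
  ts <- fake_ts(rbind(tip), rbind(c(0, 1, 0)), n_peritumoral = 1)
  mask <- rasterize_ablations(ts, params, scene)
  met <- coverage_metrics(mask, scene, ts)

  # independent oracle: direct voxel counting from the label grid
  lab <- scene$labels
  tm <- lab == scene_labels[["tumor"]] | lab == scene_labels[["margin"]]
  expect_equal(met$M, sum(mask & tm) / sum(tm), tolerance = 1e-12)
  expect_equal(met$H, sum(mask & !tm) / sum(mask), tolerance = 1e-12)
  expect_equal(met$efficiency, 1 - met$H, tolerance = 1e-12)
  expect_gt(met$M, 0); expect_lt(met$M, 1)   # genuinely partial overlap
})

test_that("perfect and disjoint ablation masks give the boundary metrics", {
  scene <- bare_sphere_scene(tumor_radius = 6, voxel = 1, margin = 5,
                             half_extent = 30)
  lab <- scene$labels
  tm <- lab == scene_labels[["tumor"]] | lab == scene_labels[["margin"]]
  ts <- fake_ts(rbind(c(0, 0, 0)), rbind(c(0, 1, 0)), n_peritumoral = 1)

  met1 <- coverage_metrics(tm, scene, ts)
  expect_equal(met1$M, 1); expect_equal(met1$H, 0)
  expect_equal(met1$efficiency, 1)

  outside <- array(FALSE, dim(lab)); outside[1:5, 1:5, 1:5] <- TRUE
  met0 <- coverage_metrics(outside, scene, ts)
  expect_equal(met0$M, 0); expect_equal(met0$H, 1)

  met_empty <- coverage_metrics(array(FALSE, dim(lab)), scene, ts)
  expect_equal(met_empty$M, 0); expect_equal(met_empty$H, 0)
})

test_that("adding an ablation is monotone in M and ablated volume", {
  scene <- bare_sphere_scene(tumor_radius = 6, voxel = 1, margin = 5,
                             half_extent = 30)
  params <- ablation_params(a_long_mm = 10, b_trans_mm = 8)
  base_tips <- rbind(c(0, 2, 0))
  more_tips <- rbind(base_tips, c(5, -3, 2))
  m1 <- rasterize_ablations(fake_ts(base_tips, rbind(c(0, 1, 0))),
                            params, scene)
  m2 <- rasterize_ablations(fake_ts(more_tips,
                                    rbind(c(0, 1, 0), c(1, 0, 0))),
                            params, scene)
  expect_true(all(m2[m1]))
  lab <- scene$labels
  tm <- lab == scene_labels[["tumor"]] | lab == scene_labels[["margin"]]
  expect_gte(sum(m2 & tm), sum(m1 & tm))
  expect_gte(sum(m2), sum(m1))
})

test_that("prox/dist tips are symmetric about a centered sphere tumor", {
  scene <- easy_scene(); entries <- easy_entries()
  cfg <- planning_configuration(8, 1, 30, 0, variant = "both")
  ts <- build_plan_trajectories(cfg, entries, scene, arc_needle_spec())
  ctr <- label_centroid(scene, "tumor")
  d <- sweep(ts$internal_tips, 2, ctr, "-")
  # both tips on the straight axis, roughly mirrored through the center
  t_along <- d %*% ts$shaft_dir
  expect_equal(sum(t_along), 0, tolerance = 2 * max(scene$voxel_size))
})

test_that("variant ablations never reduce coverage", {
  scene <- easy_scene(); entries <- easy_entries()
  params <- ablation_params()
  spec <- arc_needle_spec()
  base <- build_plan_trajectories(planning_configuration(8, 2, 30, 0.1),
                                  entries, scene, spec)
  with_v <- build_plan_trajectories(
    planning_configuration(8, 2, 30, 0.1, variant = "both"),
    entries, scene, spec)
  m_base <- rasterize_ablations(base, params, scene)
  m_v <- rasterize_ablations(with_v, params, scene)
  expect_true(all(m_v[m_base]))
})
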