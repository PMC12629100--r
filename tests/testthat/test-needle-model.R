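# Curved-tip construction: arc geometry, symmetry, equivariance.

test_that("locked joints give a straight 19 mm tip", {
  spec <- arc_needle_spec(joint_max_bend_deg = 0)
  tip <- build_curved_tip(c(0, 0, 0), c(0, 0, 1), 0, spec,
                          resample_step_mm = NA)
  expect_equal(tip$tip, c(0, 0, 19), tolerance = 1e-12)
  # collinear with the shaft
  expect_true(all(abs(tip$polyline[, 1:2]) < 1e-12))
  expect_equal(vec_norm(tip$final_tangent - c(0, 0, 1)), 0, tolerance = 1e-12)
})

test_that("final tangent deflection equals joints x per-joint bend", {
  spec <- arc_needle_spec()      # 5 joints x 6 degrees
  shaft <- unit_vector(c(0.2, -0.4, 0.9))
  tip <- build_curved_tip(c(5, 5, 5), shaft, 1.1, spec)
  ang <- acos(min(max(sum(tip$final_tangent * shaft), -1), 1)) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-9)

  # oracle: explicit product of five 6-degree rotation matrices
  rotmat <- function(axis, th) {
    k <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  bend_dir <- rotate_about_axis(reference_normal(shaft), shaft, 1.1)
  axis <- c(shaft[2] * bend_dir[3] - shaft[3] * bend_dir[2],
            shaft[3] * bend_dir[1] - shaft[1] * bend_dir[3],
            shaft[1] * bend_dir[2] - shaft[2] * bend_dir[1])
  R <- rotmat(axis, 6 * pi / 180)
  expected <- shaft
  for (j in 1:5) expected <- drop(R %*% expected)
  expect_equal(tip$final_tangent, expected, tolerance = 1e-9)

  # per-joint deflection is exactly j x 6 degrees
  spec_j <- arc_needle_spec()
  tangents <- Reduce(function(tau, j) drop(R %*% tau), 1:5,
                     accumulate = TRUE, init = shaft)[-1]
  for (j in 1:5) {
    a <- acos(min(max(sum(tangents[[j]] * shaft), -1), 1)) * 180 / pi
    expect_equal(a, j * 6, tolerance = 1e-9)
  }
})

test_that("opposite plane angles mirror the branch across the shaft", {
  spec <- arc_needle_spec()
  shaft <- c(0, 0, 1)
  a <- build_curved_tip(c(0, 0, 0), shaft, 0.7, spec, resample_step_mm = NA)
  b <- build_curved_tip(c(0, 0, 0), shaft, 0.7 + pi, spec,
                        resample_step_mm = NA)
  # mirror through the shaft axis: lateral components flip, axial agree
  lat_a <- a$polyline[, 1:2]; lat_b <- b$polyline[, 1:2]
  expect_equal(lat_a, -lat_b, tolerance = 1e-9)
  expect_equal(a$polyline[, 3], b$polyline[, 3], tolerance = 1e-9)
})

test_that("every branch point stays within the tip arc length of the flexion point", {
  spec <- arc_needle_spec()
  for (ang in c(0, 1, 2.5, 4)) {
    tip <- build_curved_tip(c(1, 2, 3), unit_vector(c(1, 1, 1)), ang, spec)
    d <- sqrt(rowSums(sweep(tip$polyline, 2, c(1, 2, 3), "-")^2))
    expect_true(all(d <= (spec$n_joints - 1) * spec$joint_spacing_mm +
                      spec$distal_length_mm + 1e-9))
  }
})

test_that("plan trajectories share the flexion point and spread branches evenly", {
  scene <- easy_scene(); entries <- easy_entries()
  cfg <- planning_configuration(5, 4, 30, 0.2)
  ts <- build_plan_trajectories(cfg, entries, scene, arc_needle_spec())
  expect_length(ts$branches, 4)
  for (b in ts$branches) {
    expect_equal(b$polyline[1, ], ts$flexion_point, tolerance = 1e-12)
  }
  angles <- vapply(ts$branches, function(b) b$plane_angle, numeric(1))
  expect_equal(diff(angles), rep(2 * pi / 4, 3), tolerance = 1e-12)
  expect_equal(angles[1], 0.2, tolerance = 1e-12)
})

test_that("rotating the shift rotates all branches rigidly about the shaft", {
  scene <- easy_scene(); entries <- easy_entries()
  delta <- 0.31
  cfg1 <- planning_configuration(10, 3, 28, 0.1)
  cfg2 <- planning_configuration(10, 3, 28, 0.1 + delta)
  spec <- arc_needle_spec()
  t1 <- build_plan_trajectories(cfg1, entries, scene, spec)
  t2 <- build_plan_trajectories(cfg2, entries, scene, spec)
  axis <- t1$shaft_dir
  for (k in 1:3) {
    p1 <- t1$branches[[k]]$polyline
    p2 <- t2$branches[[k]]$polyline
    rel1 <- sweep(p1, 2, t1$flexion_point, "-")
    rel2 <- sweep(p2, 2, t2$flexion_point, "-")
    expect_equal(rotate_about_axis(rel1, axis, delta), rel2,
                 tolerance = 1e-9)
  }
})

test_that("variants add the advertised catheter tips deterministically", {
  scene <- easy_scene(); entries <- easy_entries()
  spec <- arc_needle_spec()
  for (v in c("none", "prox", "dist", "both")) {
    cfg <- planning_configuration(8, 2, 30, 0.05, variant = v)
    ts <- build_plan_trajectories(cfg, entries, scene, spec)
    extra <- switch(v, none = 0L, prox = 1L, dist = 1L, both = 2L)
    expect_identical(n_ablation_tips(ts), 2L + extra)
  }
  cfg <- planning_configuration(8, 2, 30, 0.05, variant = "both")
  a <- build_plan_trajectories(cfg, entries, scene, spec)
  b <- build_plan_trajectories(cfg, entries, scene, spec)
  expect_identical(a$catheter_tips, b$catheter_tips)
  expect_identical(a$branches[[1]]$polyline, b$branches[[1]]$polyline)
})

test_that("internal ablation tips land inside the tumor", {
  scene <- easy_scene(); entries <- easy_entries()
  cfg <- planning_configuration(8, 1, 30, 0, variant = "both")
  ts <- build_plan_trajectories(cfg, entries, scene, arc_needle_spec())
  expect_identical(unname(labels_at(scene, ts$internal_tips)),
                   rep(scene_labels[["tumor"]], 2))
})

test_that("degenerate shaft direction errors", {
  expect_error(build_curved_tip(c(0, 0, 0), c(0, 0, 0), 0, arc_needle_spec()),
               "degenerate")
})
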