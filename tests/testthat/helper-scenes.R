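# Shared fixtures: phantom scenes and derived products are expensive enough
# to build once per test run and memoize here.

.fixture_env <- new.env(parent = emptyenv())

# internal helpers exercised directly by tests
vec_norm <- arcplan:::vec_norm
unit_vector <- arcplan:::unit_vector
min_cross_distance <- arcplan:::min_cross_distance
liverish_labels <- arcplan:::liverish_labels

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

easy_scene <- function() {
  fixture("easy", function() make_test_suite_scenes(voxel_mm = 2,
                                                    which = "easy")[[1]])
}

easy_entries <- function() {
  fixture("easy_entries", function() generate_entry_candidates(easy_scene()))
}

easy_obstacles <- function() {
  fixture("easy_obstacles", function() obstacle_set(easy_scene()))
}

narrow_scene <- function() {
  fixture("narrow", function() make_test_suite_scenes(voxel_mm = 2,
                                                      which = "narrow")[[1]])
}

blocked_scene <- function() {
  fixture("blocked", function() make_test_suite_scenes(voxel_mm = 2,
                                                       which = "blocked")[[1]])
}

# A minimal scene with one spherical tumor inside a big liver and no
# obstacles; used by geometry-level tests.
bare_sphere_scene <- function(tumor_radius = 6.2, voxel = 1, margin = 10,
                              half_extent = 30) {
  fixture(sprintf("bare_%g_%g_%g", tumor_radius, voxel, margin), function() {
    n <- 2 * half_extent / voxel + 1
    spec <- phantom_spec(
      grid_shape = rep(n, 3), voxel_size_mm = voxel,
      body_semiaxes_mm = rep(half_extent - 1, 3), body_exponent = 2,
      liver_center_mm = c(0, 0, 0),
      liver_semiaxes_mm = rep(half_extent - 3, 3),
      tumor_center_mm = c(0, 0, 0),
      tumor_semiaxes_mm = rep(tumor_radius, 3),
      n_vessels = 0, vessel_region = list(), ribs = list(),
      margin_mm = margin, seed = 1L)
    generate_phantom(spec)
  })
}

# Discretized planning space on the easy phantom: 3 entries x N in 1..4 x
# 5 flexion depths x 4 shifts (240 configurations), shared evaluation cache.
discrete_space <- function() {
  fixture("discrete_space", function() {
    scene <- easy_scene()
    entries <- easy_entries()
    E <- nrow(entries$points)
    entry_grid <- round(seq(1, E - 1, length.out = 3))
    f_lo <- 15
    f_hi <- min(entries$dist_to_margin[entry_grid + 1]) - 2
    depth_grid <- seq(f_lo, f_hi, length.out = 5)
    bounds <- search_space_bounds(
      min = c(0, 1, f_lo, 0),
      max = c(E - 1, 4, f_hi, 1),
      kind = c("integer-index", "integer", "continuous", "normalized-angle"),
      names = c("entry_index", "n_ablations", "flexion_depth_mm", "shift_norm"),
      grid = list(entry_grid, 1:4, depth_grid, c(0, 0.25, 0.5, 0.75)))
    cache <- new.env(parent = emptyenv())
    exhaustive <- enumerate_space(scene, entries, bounds,
                                  variant = "none",
                                  obstacles = easy_obstacles(), cache = cache)
    list(bounds = bounds, cache = cache, exhaustive = exhaustive)
  })
}

expect_feasible_plan <- function(res) {
  expect_identical(res$status, "ok")
  expect_true(res$best_metrics$feasible)
  expect_length(res$best_metrics$violations, 0)
}
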