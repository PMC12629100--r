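# Swarm optimizer: decoding, velocity scenarios, bouncing bounds, core loop.

dummy_entries <- function(E = 10) {
  structure(list(points = matrix(0, E, 3), normals = matrix(0, E, 3),
                 directions = matrix(rep(c(0, 1, 0), E), E, 3, byrow = TRUE),
                 dist_to_margin = rep(60, E), tumor_centroid = c(0, 0, 0)),
            class = "entry_point_set")
}

test_that("particle decoding rounds, clamps and rescales the shift", {
  e <- dummy_entries(10)
  b <- planner_bounds(e)
  cfg <- decode_particle(c(2.2, 3.4, 25, 0.5), b, e)
  expect_identical(cfg$n_ablations, 3L)
  cfg <- decode_particle(c(2.2, 3.6, 25, 0.5), b, e)
  expect_identical(cfg$n_ablations, 4L)
  cfg <- decode_particle(c(0, 4, 25, 1.0), b, e)
  expect_equal(cfg$rotation_shift_rad, pi / 2, tolerance = 1e-12)
  # round trip on integer-consistent positions
  cfg0 <- planning_configuration(3, 5, 33.5, 0.4 * 2 * pi / 5)
  x <- encode_particle(cfg0, b)
  cfg1 <- decode_particle(x, b, e)
  expect_equal(unclass(cfg1), unclass(cfg0), tolerance = 1e-12)
})

test_that("velocity updates reproduce the hand-evaluated scenarios", {
  p <- psam_params()
  # fixed point: at the optimum with zero velocity nothing moves
  expect_equal(update_velocity(0, 3, pbest = 3, gbest = 3, params = p), 0)
  # inertia only: v=1, x=pbest=gbest=3 -> v' = w = 0.724 regardless of mu
  expect_equal(update_velocity(1, 3, pbest = 3, gbest = 3, params = p),
               0.724, tolerance = 1e-12)
  # memory pull: mu3=1, rhistory-x=2, other terms cancel -> 1.468*2 = 2.936
  expect_equal(update_velocity(0, 1, pbest = 1, gbest = 1, rhistory = 3,
                               params = p, mu3 = 1),
               2.936, tolerance = 1e-12)
  # undefined pbest/gbest cancel their terms
  expect_equal(update_velocity(2, 5, params = p), p$w * 2, tolerance = 1e-12)
})

test_that("bouncing bounds reflect overshoots back inside", {
  b <- search_space_bounds(0, 10, "continuous")
  expect_equal(apply_bouncing_bounds(-2, b), 2)
  expect_equal(apply_bouncing_bounds(11, b), 9)
  expect_equal(apply_bouncing_bounds(5, b), 5)
  # boundary involution
  expect_equal(apply_bouncing_bounds(0, b), 0)
  expect_equal(apply_bouncing_bounds(10, b), 10)
})

test_that("bouncing bounds land inside for random overshoots", {
  b <- search_space_bounds(c(-1, 0), c(2, 10),
                           c("continuous", "continuous"))
  set.seed(99)
  n <- 10000
  width <- b$max - b$min
  x <- cbind(runif(n, b$min[1] - width[1], b$max[1] + width[1]),
             runif(n, b$min[2] - width[2], b$max[2] + width[2]))
  y <- apply_bouncing_bounds(x, b)
  expect_true(all(y[, 1] >= b$min[1] - 1e-12 & y[, 1] <= b$max[1] + 1e-12))
  expect_true(all(y[, 2] >= b$min[2] - 1e-12 & y[, 2] <= b$max[2] + 1e-12))
  # interior points untouched
  inside <- x[, 1] >= b$min[1] & x[, 1] <= b$max[1]
  expect_equal(y[inside, 1], x[inside, 1])
})

test_that("the swarm solves an unconstrained smooth objective (plain PSO)", {
  target <- c(1, -2, 0.5, 2)
  obj <- function(x) list(feasible = TRUE, score = -sum((x - target)^2))
  b <- search_space_bounds(rep(-5, 4), rep(5, 4), rep("continuous", 4))
  hits <- 0
  for (seed in 1:20) {
    r <- psam_optimize(obj, b, psam_params(), seed = seed)
    if (sqrt(sum((r$best_x - target)^2)) <= 1e-2) hits <- hits + 1
  }
  expect_gte(hits, 18)   # >= 90% of seeds
})

test_that("gbest is monotone, bounded, and stagnation controls run length", {
  obj <- function(x) list(feasible = TRUE,
                          score = -sum(x^2) + sin(40 * x[1]))
  b <- search_space_bounds(c(-3, -3), c(3, 3), rep("continuous", 2))
  p <- psam_params(stagnation_limit = 30, max_iter = 200)
  r <- psam_optimize(obj, b, p, seed = 5)
  g <- r$history$gbest_score
  expect_true(all(diff(g) >= -1e-12))
  expect_gte(r$n_iter, 30)
  expect_lte(r$n_iter, 200)
  tail_stag <- r$history$stagnation[r$n_iter]
  expect_true(tail_stag == 30 || r$n_iter == 200)
})

test_that("infeasible space yields a clean no-feasible-plan result", {
  obj <- function(x) list(feasible = FALSE, score = NA)
  b <- search_space_bounds(c(0, 0), c(1, 1), rep("continuous", 2))
  r <- psam_optimize(obj, b, psam_params(stagnation_limit = 10), seed = 1)
  expect_identical(r$status, "no feasible plan")
  expect_identical(r$best_score, -Inf)
  expect_identical(r$n_iter, 10L)
})

test_that("memory only ever holds feasible positions and guides recovery", {
  # feasible only in the left half; score favors the right edge of it
  obj <- function(x) {
    feas <- x[1] <= 0.5
    list(feasible = feas, score = if (feas) x[1] else NA)
  }
  b <- search_space_bounds(0, 1, "continuous")
  r <- psam_optimize(obj, b, psam_params(stagnation_limit = 40), seed = 3)
  expect_identical(r$status, "ok")
  expect_lte(r$best_x[1], 0.5)
  expect_equal(r$best_score, 0.5, tolerance = 1e-3)
})

test_that("identical seeds reproduce identical histories", {
  obj <- function(x) list(feasible = x[1] + x[2] < 4,
                          score = -sum((x - 1)^2))
  b <- search_space_bounds(c(-3, -3), c(3, 3), rep("continuous", 2))
  p <- psam_params(stagnation_limit = 20, max_iter = 60)
  r1 <- psam_optimize(obj, b, p, seed = 11)
  r2 <- psam_optimize(obj, b, p, seed = 11)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_x, r2$best_x)
  r3 <- psam_optimize(obj, b, p, seed = 12)
  expect_false(identical(r1$history, r3$history))
})
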