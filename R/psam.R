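#' PSAM optimizer parameters
#'
#' Swarm parameters of the memory-augmented constrained particle swarm:
#' inertia `w = 0.724` and cognitive/social/memory coefficients
#' `c1 = c2 = c3 = 1.468` (a standard fast-converging PSO setting), eight
#' particles, and termination after 50 iterations without improvement of the
#' global best.
#'
#' @param w inertia weight in (0, 1).
#' @param c1,c2,c3 cognitive, social and memory-attraction coefficients.
#' @param n_particles swarm size.
#' @param stagnation_limit iterations without strict gbest improvement before
#'   stopping.
#' @param max_iter hard iteration cap (>= `stagnation_limit`), bounding runs
#'   on objectives where strict improvements never cease.
#' @param memory_capacity ring-buffer capacity of the feasible-solution memory.
#' @param shared_mu draw one uniform per term (scalar mu) instead of one per
#'   dimension.
#' @export
psam_params <- function(w = 0.724, c1 = 1.468, c2 = 1.468, c3 = 1.468,
                        n_particles = 8, stagnation_limit = 50,
                        max_iter = 400, memory_capacity = 256,
                        shared_mu = FALSE) {
  stopifnot(w > 0, w < 1, c1 > 0, c2 > 0, c3 > 0, n_particles >= 1,
            stagnation_limit >= 1, max_iter >= stagnation_limit)
  structure(list(w = w, c1 = c1, c2 = c2, c3 = c3,
                 n_particles = as.integer(n_particles),
                 stagnation_limit = as.integer(stagnation_limit),
                 max_iter = as.integer(max_iter),
                 memory_capacity = as.integer(memory_capacity),
                 shared_mu = shared_mu),
            class = "psam_params")
}

#' Search-space bounds
#'
#' Per-dimension bounds of the planning search space. Dimensions are searched
#' as continuous values; integer-like dimensions are rounded only at decoding,
#' and an optional per-dimension `grid` snaps decoded values to a discrete set
#' (used for small enumerable spaces).
#'
#' @param min,max numeric vectors of per-dimension bounds (`min < max`, or
#'   `min == max` for a frozen dimension).
#' @param kind character vector: `"integer-index"`, `"integer"`,
#'   `"continuous"` or `"normalized-angle"`.
#' @param names dimension names.
#' @param grid optional list of per-dimension snap grids (`NULL` entries for
#'   continuous dimensions).
#' @export
search_space_bounds <- function(min, max, kind, names = NULL, grid = NULL) {
  stopifnot(length(min) == length(max), all(min <= max))
  structure(list(min = as.numeric(min), max = as.numeric(max),
                 kind = kind, names = names,
                 grid = if (is.null(grid)) vector("list", length(min)) else grid),
            class = "search_space_bounds")
}

#' Planner search bounds for a scene
#'
#' Dimensions: entry index in `[0, E-1]` (0-based, rounded at decode), number
#' of ablations `N` in `[1, n_max]`, flexion depth in mm, and the rotational
#' shift stored normalized in `[0, 1]` (scaled by `2*pi/N` at decode so its
#' bound is independent of N). Flexion depth spans 10 mm past the skin up to
#' the largest entry-to-margin distance minus a tip clearance.
#'
#' @param entries an `entry_point_set`.
#' @param n_max maximal ablation count (8; the Monte-Carlo baseline may cap
#'   it at 4).
#' @param f_min_mm minimal flexion depth past the skin.
#' @param tip_clearance_mm subtracted from the entry-to-margin distance for
#'   the upper flexion bound.
#' @export
planner_bounds <- function(entries, n_max = 8, f_min_mm = 10,
                           tip_clearance_mm = 2) {
  E <- nrow(entries$points)
  f_max <- max(entries$dist_to_margin) - tip_clearance_mm
  f_max <- max(f_max, f_min_mm + 1)
  search_space_bounds(
    min = c(0, 1, f_min_mm, 0),
    max = c(E - 1, n_max, f_max, 1),
    kind = c("integer-index", "integer", "continuous", "normalized-angle"),
    names = c("entry_index", "n_ablations", "flexion_depth_mm", "shift_norm")
  )
}

#' Decode a particle position into a planning configuration
#'
#' Entry index and N are rounded (half away from zero) and clamped; the
#' normalized shift is scaled by `2*pi/N`; optional snap grids discretize any
#' dimension. Decoding is the only place integrality enters: the swarm itself
#' moves through a continuous relaxation of the space.
#'
#' @param x numeric position vector (entry0, N, depth, shift_norm).
#' @param bounds a [search_space_bounds()].
#' @param entries an `entry_point_set` (for the entry count).
#' @param variant variant flag carried into the configuration.
#' @export
decode_particle <- function(x, bounds, entries, variant = "none") {
  snap <- function(val, g) if (is.null(g)) val else g[which.min(abs(g - val))]
  e0 <- round(snap(x[1], bounds$grid[[1]]))
  e0 <- min(max(e0, 0), nrow(entries$points) - 1)
  N <- round(snap(x[2], bounds$grid[[2]]))
  N <- min(max(N, 1), 8)
  depth <- snap(min(max(x[3], bounds$min[3]), bounds$max[3]), bounds$grid[[3]])
  sh <- snap(min(max(x[4], 0), 1), bounds$grid[[4]])
  planning_configuration(entry_index = e0 + 1, n_ablations = N,
                         flexion_depth_mm = depth,
                         rotation_shift_rad = sh * 2 * pi / N,
                         variant = variant)
}

#' Encode a planning configuration as a particle position
#' @inheritParams decode_particle
#' @param config a [planning_configuration()].
#' @export
encode_particle <- function(config, bounds) {
  c(config$entry_index - 1, config$n_ablations,
    config$flexion_depth_mm,
    config$rotation_shift_rad * config$n_ablations / (2 * pi))
}

#' One velocity update
#'
#' The three update scenarios of the memory-augmented swarm:
#' \enumerate{
#'   \item feasible particle: inertia + cognitive + social pull
#'     (`v' = w v + c1 mu1 (pbest - x) + c2 mu2 (gbest - x)`);
#'   \item infeasible particle, empty memory: the particle is reinitialized
#'     uniformly at random within bounds (handled by the caller; this
#'     function is not used);
#'   \item infeasible particle, nonempty memory: an additional pull
#'     `c3 mu3 (rhistory - x)` toward a uniformly drawn remembered feasible
#'     position.
#' }
#' Undefined pbest/gbest default to the particle's current position, which
#' cancels the corresponding term.
#'
#' @param v,x current velocity and position.
#' @param pbest,gbest personal/global best positions (`NULL` when undefined).
#' @param rhistory remembered feasible position (`NULL` outside scenario 3).
#' @param params a [psam_params()].
#' @param mu1,mu2,mu3 optional fixed uniforms (for testing); drawn fresh per
#'   dimension (or shared, see `shared_mu`) when `NULL`.
#' @export
update_velocity <- function(v, x, pbest = NULL, gbest = NULL, rhistory = NULL,
                            params = psam_params(),
                            mu1 = NULL, mu2 = NULL, mu3 = NULL) {
  d <- length(x)
  draw <- function(mu) {
    if (!is.null(mu)) rep_len(mu, d)
    else if (params$shared_mu) rep(stats::runif(1), d)
    else stats::runif(d)
  }
  if (is.null(pbest)) pbest <- x
  if (is.null(gbest)) gbest <- x
  vn <- params$w * v +
    params$c1 * draw(mu1) * (pbest - x) +
    params$c2 * draw(mu2) * (gbest - x)
  if (!is.null(rhistory)) {
    vn <- vn + params$c3 * draw(mu3) * (rhistory - x)
  }
  vn
}

#' Reflect a position back inside its bounds ("bouncing bounds")
#'
#' An overshoot past a dimension's limit is reflected back inside
#' (`x' = min + (min - x)` below, `x' = max - (x - max)` above) instead of
#' clamped, preserving exploratory velocity near the limits. Reflection is
#' repeated until the coordinate lies inside.
#'
#' @param x position vector (or matrix of row positions).
#' @param bounds a [search_space_bounds()].
#' @export
apply_bouncing_bounds <- function(x, bounds) {
  single <- is.null(dim(x))
  m <- if (single) matrix(x, nrow = 1) else x
  for (j in seq_len(ncol(m))) {
    lo <- bounds$min[j]; hi <- bounds$max[j]
    if (hi <= lo) { m[, j] <- lo; next }
    repeat {
      below <- m[, j] < lo
      above <- m[, j] > hi
      if (!any(below) && !any(above)) break
      m[below, j] <- 2 * lo - m[below, j]
      m[above, j] <- 2 * hi - m[above, j]
    }
  }
  if (single) drop(m) else m
}

#' Run the memory-augmented particle swarm on an arbitrary objective
#'
#' Core loop, independent of the planning domain: evaluates particles,
#' maintains personal/global bests over feasible evaluations only, stores
#' every new feasible personal/global best in a bounded memory, applies the
#' three scenario velocity updates and the bouncing bounds, and stops after
#' `stagnation_limit` iterations without strict gbest improvement (or at
#' `max_iter`).
#'
#' @param objective `function(x)` returning `list(feasible =, score =)`
#'   (score used only when feasible).
#' @param bounds a [search_space_bounds()].
#' @param params a [psam_params()].
#' @param seed integer seed; the run is fully reproducible.
#' @return list with `best_x`, `best_score` (`NULL`/`-Inf` when no feasible
#'   point was ever found), `history` (per-iteration data.frame), `n_iter`,
#'   `status`.
#' @export
psam_optimize <- function(objective, bounds, params = psam_params(), seed = 1L) {
  d <- length(bounds$min)
  np <- params$n_particles
  with_local_seed(seed, {
    X <- sapply(seq_len(d), function(j)
      stats::runif(np, bounds$min[j], bounds$max[j]))
    X <- matrix(X, nrow = np)
    V <- matrix(0, np, d)
    pbest_x <- matrix(NA_real_, np, d)
    pbest_s <- rep(-Inf, np)
    gbest_x <- NULL
    gbest_s <- -Inf
    memory <- list()
    mem_next <- 1L
    push_memory <- function(x, s) {
      memory[[mem_next]] <<- list(x = x, score = s)
      mem_next <<- if (mem_next >= params$memory_capacity) 1L else mem_next + 1L
    }
    stagnation <- 0L
    hist <- vector("list", params$max_iter)
    t <- 0L
    while (t < params$max_iter && stagnation < params$stagnation_limit) {
      t <- t + 1L
      feas <- logical(np)
      for (i in seq_len(np)) {
        ev <- objective(X[i, ])
        feas[i] <- isTRUE(ev$feasible)
        if (feas[i]) {
          if (ev$score > pbest_s[i]) {
            pbest_x[i, ] <- X[i, ]
            pbest_s[i] <- ev$score
            push_memory(X[i, ], ev$score)
          }
        }
      }
      # synchronous gbest update; stagnation resets only on strict improvement
      ib <- which.max(pbest_s)
      if (is.finite(pbest_s[ib]) && pbest_s[ib] > gbest_s) {
        gbest_s <- pbest_s[ib]
        gbest_x <- pbest_x[ib, ]
        push_memory(gbest_x, gbest_s)
        stagnation <- 0L
      } else {
        stagnation <- stagnation + 1L
      }
      hist[[t]] <- data.frame(iteration = t, gbest_score = gbest_s,
                              n_feasible = sum(feas),
                              memory_size = length(memory),
                              stagnation = stagnation)
      # velocity/position updates per scenario
      for (i in seq_len(np)) {
        if (feas[i]) {
          pb <- if (is.finite(pbest_s[i])) pbest_x[i, ] else NULL
          gb <- gbest_x
          V[i, ] <- update_velocity(V[i, ], X[i, ], pb, gb, NULL, params)
          X[i, ] <- X[i, ] + V[i, ]
        } else if (length(memory) == 0) {
          # scenario 2: full restart of the particle
          X[i, ] <- sapply(seq_len(d), function(j)
            stats::runif(1, bounds$min[j], bounds$max[j]))
          V[i, ] <- 0
          pbest_x[i, ] <- NA_real_
          pbest_s[i] <- -Inf
        } else {
          rh <- memory[[sample.int(length(memory), 1)]]$x
          pb <- if (is.finite(pbest_s[i])) pbest_x[i, ] else NULL
          gb <- gbest_x
          V[i, ] <- update_velocity(V[i, ], X[i, ], pb, gb, rh, params)
          X[i, ] <- X[i, ] + V[i, ]
        }
      }
      X <- apply_bouncing_bounds(X, bounds)
    }
    list(best_x = gbest_x,
         best_score = if (is.finite(gbest_s)) gbest_s else -Inf,
         history = do.call(rbind, hist[seq_len(t)]),
         n_iter = t,
         status = if (is.null(gbest_x)) "no feasible plan" else "ok")
  })
}

#' Plan-evaluation closure with memoization
#'
#' Builds the objective used by both optimizers: decode the particle, build
#' the trajectories, check hard-constraint feasibility, and (when feasible)
#' rasterize the ablations and score the plan. Evaluations are memoized on
#' the decoded configuration, which is exact because evaluation is
#' deterministic.
#'
#' @param scene an `anatomy_scene`.
#' @param entries an `entry_point_set`.
#' @param needle_spec,abl_params,weights planner components.
#' @param variant plan variant.
#' @param bounds the bounds used for decoding.
#' @param obstacles pre-built obstacle set (built once if `NULL`).
#' @param cache optional environment shared between optimizers.
#' @return `function(x)` returning
#'   `list(feasible, score, config, metrics, violations)`.
#' @export
make_plan_evaluator <- function(scene, entries, needle_spec = arc_needle_spec(),
                                abl_params = ablation_params(),
                                weights = score_weights(),
                                variant = "none", bounds = NULL,
                                obstacles = NULL, cache = NULL) {
  if (is.null(bounds)) bounds <- planner_bounds(entries)
  if (is.null(obstacles)) obstacles <- obstacle_set(scene, include_bones = TRUE)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  force(scene); force(entries); force(needle_spec); force(abl_params)
  force(weights); force(variant)
  function(x) {
    config <- decode_particle(x, bounds, entries, variant)
    key <- sprintf("%d|%d|%.6f|%.8f|%s", config$entry_index,
                   config$n_ablations, config$flexion_depth_mm,
                   config$rotation_shift_rad, config$variant)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ts <- build_plan_trajectories(config, entries, scene, needle_spec)
    fz <- check_feasibility(ts, scene, needle_spec, obstacles)
    out <- if (!fz$feasible) {
      list(feasible = FALSE, score = -Inf, config = config,
           metrics = NULL, violations = fz$violations)
    } else {
      mask <- rasterize_ablations(ts, abl_params, scene)
      met <- coverage_metrics(mask, scene, ts, obstacles, weights)
      met$feasible <- TRUE
      list(feasible = TRUE, score = compute_score(met, weights),
           config = config, metrics = met, violations = character(0))
    }
    cache[[key]] <- out
    out
  }
}

#' Run the full planner on a scene
#'
#' End-to-end constrained swarm optimization of the planning score for one
#' scene and variant: decode, build trajectories, check feasibility, score,
#' memory-augmented updates, bouncing bounds, stagnation stopping.
#'
#' @param scene an `anatomy_scene`.
#' @param entries an `entry_point_set` (from [generate_entry_candidates()]).
#' @param needle_spec,abl_params,weights planner components.
#' @param params a [psam_params()].
#' @param variant `"none"`, `"prox"`, `"dist"` or `"both"`.
#' @param seed integer seed.
#' @param bounds optional [search_space_bounds()] (e.g. discretized).
#' @param obstacles,cache optional precomputed obstacle set / shared cache.
#' @return list with `status`, `best_config`, `best_metrics`, `best_score`,
#'   `history`, `n_iter`, `seed`.
#' @export
run_psam <- function(scene, entries, needle_spec = arc_needle_spec(),
                     abl_params = ablation_params(),
                     weights = score_weights(),
                     params = psam_params(), variant = "none", seed = 1L,
                     bounds = NULL, obstacles = NULL, cache = NULL) {
  if (is.null(bounds)) bounds <- planner_bounds(entries)
  evalr <- make_plan_evaluator(scene, entries, needle_spec, abl_params,
                               weights, variant, bounds, obstacles, cache)
  res <- psam_optimize(evalr, bounds, params, seed)
  out <- list(status = res$status, best_score = res$best_score,
              history = res$history, n_iter = res$n_iter, seed = seed,
              variant = variant)
  if (res$status == "ok") {
    best <- evalr(res$best_x)
    out$best_config <- best$config
    out$best_metrics <- best$metrics
    out$best_x <- res$best_x
  } else {
    out$diagnostics <- sprintf(
      "no feasible configuration found in %d iterations (%d particles)",
      res$n_iter, params$n_particles)
  }
  out
}
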