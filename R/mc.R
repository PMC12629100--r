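#' Monte-Carlo baseline configuration
#'
#' @param n_samples number of uniformly drawn configurations (default 1000).
#' @param cap_N_at_4_if_coverable bound the ablation count to 4 when a single
#'   theoretical ablation volume could cover the tumor-plus-margin (reduces
#'   sampling noise on small targets).
#' @export
mc_config <- function(n_samples = 1000, cap_N_at_4_if_coverable = TRUE) {
  stopifnot(n_samples >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 cap_N_at_4_if_coverable = cap_N_at_4_if_coverable),
            class = "mc_config")
}

#' Could one ablation volume cover the tumor and margin?
#'
#' Orientation-free sufficient test: `TRUE` iff every tumor-plus-margin voxel
#' center lies within the ellipsoid's smaller (transverse) semi-axis of the
#' tumor centroid, i.e. the target fits in the ellipsoid's inscribed sphere
#' centered on the tumor.
#'
#' @param scene an `anatomy_scene` with margin built.
#' @param abl_params an [ablation_params()].
#' @export
single_ablation_coverable <- function(scene, abl_params = ablation_params()) {
  tm <- scene$labels == scene_labels[["tumor"]] |
        scene$labels == scene_labels[["margin"]]
  if (!any(tm)) return(FALSE)
  centroid <- label_centroid(scene, "tumor")
  pts <- mask_voxel_centers(scene, tm)
  r2 <- rowSums(sweep(pts, 2, centroid, "-")^2)
  all(r2 <= min(abl_params$a_long_mm, abl_params$b_trans_mm)^2)
}

#' Semi-exhaustive Monte-Carlo baseline planner
#'
#' Draws `n_samples` planning configurations uniformly over the bounded
#' search space (integer dimensions uniform over their integer range,
#' continuous dimensions uniform, snap grids respected), evaluates each with
#' the same feasibility check and score as the swarm planner, and returns the
#' best feasible plan. Infeasible draws count toward the sample budget but
#' yield no score. Sampling is sequential, so with a common seed the first k
#' draws of a larger run replicate a smaller one.
#'
#' @inheritParams run_psam
#' @param config an [mc_config()].
#' @return list with `status`, `best_config`, `best_metrics`, `best_score`,
#'   `all_scores` (NA for infeasible draws), `n_feasible`, `seed`.
#' @export
run_monte_carlo <- function(scene, entries, needle_spec = arc_needle_spec(),
                            abl_params = ablation_params(),
                            weights = score_weights(),
                            config = mc_config(), variant = "none", seed = 1L,
                            bounds = NULL, obstacles = NULL, cache = NULL) {
  if (is.null(bounds)) {
    n_max <- if (config$cap_N_at_4_if_coverable &&
                 single_ablation_coverable(scene, abl_params)) 4 else 8
    bounds <- planner_bounds(entries, n_max = n_max)
  }
  evalr <- make_plan_evaluator(scene, entries, needle_spec, abl_params,
                               weights, variant, bounds, obstacles, cache)
  d <- length(bounds$min)
  with_local_seed(seed, {
    scores <- rep(NA_real_, config$n_samples)
    best <- NULL
    best_score <- -Inf
    for (k in seq_len(config$n_samples)) {
      x <- numeric(d)
      for (j in seq_len(d)) {
        g <- bounds$grid[[j]]
        if (!is.null(g)) {
          x[j] <- g[sample.int(length(g), 1)]
        } else if (bounds$kind[j] %in% c("integer-index", "integer")) {
          lo <- ceiling(bounds$min[j]); hi <- floor(bounds$max[j])
          x[j] <- if (hi > lo) sample(lo:hi, 1) else lo
        } else {
          x[j] <- stats::runif(1, bounds$min[j], bounds$max[j])
        }
      }
      ev <- evalr(x)
      if (ev$feasible) {
        scores[k] <- ev$score
        if (ev$score > best_score) {
          best_score <- ev$score
          best <- ev
        }
      }
    }
    if (is.null(best)) {
      list(status = "no feasible plan", best_score = -Inf,
           all_scores = scores, n_feasible = 0L, seed = seed,
           variant = variant,
           diagnostics = sprintf("none of %d samples feasible",
                                 config$n_samples))
    } else {
      list(status = "ok", best_config = best$config,
           best_metrics = best$metrics, best_score = best_score,
           all_scores = scores, n_feasible = sum(!is.na(scores)),
           seed = seed, variant = variant)
    }
  })
}

#' Exhaustively enumerate a discretized search space
#'
#' Reference optimum for small spaces: every dimension must carry a snap grid
#' (or be integer with a finite range). Used as the ground-truth oracle the
#' stochastic planners are compared against.
#'
#' @inheritParams run_psam
#' @param bounds a [search_space_bounds()] with grids on all dimensions.
#' @export
enumerate_space <- function(scene, entries, bounds,
                            needle_spec = arc_needle_spec(),
                            abl_params = ablation_params(),
                            weights = score_weights(), variant = "none",
                            obstacles = NULL, cache = NULL) {
  grids <- lapply(seq_along(bounds$min), function(j) {
    g <- bounds$grid[[j]]
    if (!is.null(g)) return(g)
    if (bounds$kind[j] %in% c("integer-index", "integer")) {
      return(seq(ceiling(bounds$min[j]), floor(bounds$max[j])))
    }
    stop("enumerate_space needs a grid on every continuous dimension")
  })
  combos <- as.matrix(expand.grid(grids))
  evalr <- make_plan_evaluator(scene, entries, needle_spec, abl_params,
                               weights, variant, bounds, obstacles, cache)
  scores <- rep(NA_real_, nrow(combos))
  best <- NULL; best_score <- -Inf
  for (k in seq_len(nrow(combos))) {
    ev <- evalr(combos[k, ])
    if (ev$feasible) {
      scores[k] <- ev$score
      if (ev$score > best_score) { best_score <- ev$score; best <- ev }
    }
  }
  list(best = best, best_score = best_score, scores = scores,
       n_evaluated = nrow(combos))
}
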