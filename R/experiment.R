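#' Batch comparison of planners over scenes and variants
#'
#' Runs every scene x method x variant combination and collects one row per
#' run with the reporting columns: minimum and average obstacle distance,
#' margin coverage (M, %), tumor coverage (%), efficiency (%), ablation
#' count, insertions and Score. Per-run failures (no entry point, no feasible
#' plan) are recorded as rows with a `status`, never aborting the batch.
#'
#' @param scenes named list of `anatomy_scene` objects.
#' @param methods subset of `c("psam", "mc")`.
#' @param variants subset of `c("none", "prox", "dist", "both")`.
#' @param seeds one or more integer seeds (one row per seed).
#' @param needle_spec,abl_params,weights,psam,mc planner components.
#' @param max_angle_deg entry-point incidence filter.
#' @return data.frame, one row per scene x method x variant x seed.
#' @export
run_experiment <- function(scenes, methods = c("psam", "mc"),
                           variants = c("none", "prox", "dist", "both"),
                           seeds = 1L,
                           needle_spec = arc_needle_spec(),
                           abl_params = ablation_params(),
                           weights = score_weights(),
                           psam = psam_params(), mc = mc_config(),
                           max_angle_deg = 30) {
  stopifnot(all(methods %in% c("psam", "mc")))
  stopifnot(all(variants %in% c("none", "prox", "dist", "both")))
  if (is.null(names(scenes))) names(scenes) <- paste0("scene", seq_along(scenes))
  rows <- list()
  for (sn in names(scenes)) {
    scene <- scenes[[sn]]
    entries <- tryCatch(
      generate_entry_candidates(scene, needle_spec, max_angle_deg),
      error = function(e) e)
    obstacles <- if (!inherits(entries, "error"))
      obstacle_set(scene, include_bones = TRUE) else NULL
    cache <- new.env(parent = emptyenv())
    for (m in methods) for (v in variants) for (sd in seeds) {
      row <- data.frame(scene = sn, method = m, variant = v, seed = sd,
                        status = NA_character_, score = NA_real_,
                        d_min_mm = NA_real_, d_avg_mm = NA_real_,
                        margin_coverage_pct = NA_real_,
                        tumor_coverage_pct = NA_real_,
                        efficiency_pct = NA_real_,
                        n_ablations = NA_integer_,
                        n_peritumoral = NA_integer_,
                        n_insertions = NA_integer_,
                        stringsAsFactors = FALSE)
      if (inherits(entries, "error")) {
        row$status <- conditionMessage(entries)
        rows[[length(rows) + 1L]] <- row
        next
      }
      res <- if (m == "psam") {
        run_psam(scene, entries, needle_spec, abl_params, weights, psam,
                 variant = v, seed = sd, obstacles = obstacles, cache = cache)
      } else {
        run_monte_carlo(scene, entries, needle_spec, abl_params, weights, mc,
                        variant = v, seed = sd, obstacles = obstacles,
                        cache = cache)
      }
      row$status <- res$status
      if (res$status == "ok") {
        met <- res$best_metrics
        # recompute the distance profile for the reporting-only average
        ts <- build_plan_trajectories(res$best_config, entries, scene,
                                      needle_spec)
        prof <- min_surface_distance(
          c(needle_polylines(ts), catheter_segments(ts)), obstacles,
          needle_radius(needle_spec), include_bones = FALSE,
          per_point = TRUE)
        row$score <- res$best_score
        row$d_min_mm <- met$d_min_mm
        row$d_avg_mm <- mean(prof[is.finite(prof)])
        row$margin_coverage_pct <- 100 * met$M
        row$tumor_coverage_pct <- 100 * met$tumor_coverage
        row$efficiency_pct <- 100 * met$efficiency
        row$n_ablations <- met$n_ablations_total
        row$n_peritumoral <- met$N
        row$n_insertions <- met$n_insertions
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
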