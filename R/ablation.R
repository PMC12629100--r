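#' Geometric ablation-volume parameters
#'
#' The thermal ablation is modeled purely geometrically as a prolate ellipsoid
#' of revolution around the catheter axis. Power and duration are carried as
#' metadata only (no bioheat simulation). The default 20 x 15 x 15 mm
#' semi-axes and the -a_long/3 center offset behind the catheter tip are
#' geometric placeholders representative of a 100 W / 10 min microwave
#' ablation, not vendor chart values; override them for any clinical use.
#'
#' @param a_long_mm semi-axis along the catheter axis.
#' @param b_trans_mm transverse semi-axis (the ellipsoid is rotationally
#'   symmetric, so both transverse semi-axes equal `b_trans_mm`).
#' @param center_offset_mm signed offset of the ellipsoid center from the
#'   catheter tip along its axis (negative = behind the tip).
#' @param power_W,duration_min metadata describing the emulated protocol.
#' @export
ablation_params <- function(a_long_mm = 20, b_trans_mm = 15,
                            center_offset_mm = -a_long_mm / 3,
                            power_W = 100, duration_min = 10) {
  stopifnot(a_long_mm > 0, b_trans_mm > 0)
  structure(list(a_long_mm = a_long_mm, b_trans_mm = b_trans_mm,
                 c_trans_mm = b_trans_mm,
                 center_offset_mm = center_offset_mm,
                 power_W = power_W, duration_min = duration_min),
            class = "ablation_params")
}

ellipsoid_volume_mm3 <- function(params) {
  4 / 3 * pi * params$a_long_mm * params$b_trans_mm * params$c_trans_mm
}

#' Rasterize the plan's ablation volumes
#'
#' Union of one ellipsoid per catheter tip, each oriented along its catheter
#' axis and centered `center_offset_mm` from the tip. A voxel is ablated iff
#' its center satisfies the ellipsoid inequality. Ellipsoids reaching outside
#' the grid are clipped (with a warning).
#'
#' @param trajectory_set a `trajectory_set`.
#' @param params an [ablation_params()].
#' @param scene an `anatomy_scene`.
#' @return logical 3D array on the scene grid.
#' @export
rasterize_ablations <- function(trajectory_set, params, scene) {
  dims <- dim(scene$labels)
  mask <- array(FALSE, dims)
  tips <- trajectory_set$catheter_tips
  if (is.null(tips) || nrow(tips) == 0) return(mask)
  axes <- trajectory_set$catheter_axes
  vs <- scene$voxel_size
  rad <- max(params$a_long_mm, params$b_trans_mm)
  for (i in seq_len(nrow(tips))) {
    axis <- unit_vector(axes[i, ])
    center <- tips[i, ] + axis * params$center_offset_mm
    u <- reference_normal(axis)
    v <- pracma_cross(axis, u)
    cv <- world_to_voxel(scene, rbind(center))[1, ]
    lo <- floor(cv - rad / vs); hi <- ceiling(cv + rad / vs)
    if (any(hi < 1) || any(lo > dims)) {
      warning("ablation ellipsoid entirely outside the grid; skipped")
      next
    }
    if (any(lo < 1) || any(hi > dims)) {
      warning("ablation ellipsoid clipped at the grid boundary")
    }
    lo <- pmax(lo, 1); hi <- pmin(hi, dims)
    sub <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    X <- sweep(voxel_to_world(scene, sub), 2, center, "-")
    q <- (X %*% axis / params$a_long_mm)^2 +
         (X %*% u / params$b_trans_mm)^2 +
         (X %*% v / params$c_trans_mm)^2
    inside <- drop(q) <= 1
    if (any(inside)) mask[sub[inside, , drop = FALSE]] <- TRUE
  }
  mask
}

#' Add proximal/distal in-tumor ablations
#'
#' Places up to two extra catheter tips on the straight insertion axis inside
#' the tumor: the proximal tip half a long semi-axis past the axis' tumor
#' entry, the distal tip half a long semi-axis before its tumor exit, each
#' clamped onto the tumor itself. The needle never follows: only the catheter
#' crosses the tumor, so the no-touch rule for the needle is untouched.
#'
#' @param trajectory_set a `trajectory_set`.
#' @param scene an `anatomy_scene`.
#' @param variant `"none"`, `"prox"`, `"dist"` or `"both"`.
#' @param params ablation parameters (for the half-semi-axis placement rule).
#' @return the trajectory set with internal tips appended; if the straight
#'   axis misses the tumor the variant is rejected and a violation recorded.
#' @export
place_internal_ablations <- function(trajectory_set, scene, variant,
                                     params = ablation_params()) {
  ts <- trajectory_set
  if (variant == "none") return(ts)
  dir <- ts$shaft_dir
  # sample the straight axis extended through the scene to find the tumor chord
  extent <- sum(dim(scene$labels) * scene$voxel_size)
  tmax <- min(extent, 400)
  tt <- seq(0, tmax, by = 0.5)
  pts <- matrix(ts$entry, length(tt), 3, byrow = TRUE) + outer(tt, dir)
  lab <- labels_at(scene, pts)
  on_tumor <- which(lab == scene_labels[["tumor"]])
  if (length(on_tumor) == 0) {
    ts$violations <- c(ts$violations, "variant: straight axis misses the tumor")
    return(ts)
  }
  t_in <- tt[on_tumor[1]]; t_out <- tt[on_tumor[length(on_tumor)]]
  r_half <- params$a_long_mm / 2
  clamp_to_tumor <- function(t_want) {
    t_c <- min(max(t_want, t_in), t_out)
    # snap to the nearest sampled axis position that is a tumor voxel
    cand <- tt[on_tumor]
    cand[which.min(abs(cand - t_c))]
  }
  tips <- list()
  if (variant %in% c("prox", "both")) {
    tips$prox <- ts$entry + dir * clamp_to_tumor(t_in + r_half)
  }
  if (variant %in% c("dist", "both")) {
    tips$dist <- ts$entry + dir * clamp_to_tumor(t_out - r_half)
  }
  internal <- do.call(rbind, tips)
  ts$internal_tips <- internal
  ts$catheter_tips <- rbind(ts$catheter_tips, internal)
  ts$catheter_axes <- rbind(ts$catheter_axes,
                            matrix(dir, nrow(internal), 3, byrow = TRUE))
  ts$tip_kind <- c(ts$tip_kind, names(tips))
  ts
}

#' Coverage and safety metrics of a plan
#'
#' Computes the quantities entering the plan score and the reporting table:
#' \itemize{
#'   \item `M`: fraction of the tumor-plus-margin volume that is ablated;
#'   \item `tumor_coverage`: same on the tumor alone;
#'   \item `H`: fraction of the ablated volume lying outside tumor and margin
#'     (destroyed healthy tissue); `efficiency = 1 - H`;
#'   \item `d_min_mm`: minimum distance from any needle polyline or catheter
#'     segment to any obstacle surface, minus the needle radius (bones
#'     excluded from this reported value unless `distance_includes_bones`);
#'   \item `D`: the distance penalty [distance_penalty()];
#'   \item `N`: peritumoral ablation count (the score's N);
#'     `n_ablations_total` additionally counts internal prox/dist ablations.
#' }
#' An empty ablation mask yields `M = 0, H = 0` by convention so the score is
#' defined everywhere.
#'
#' @param ablation_mask logical array from [rasterize_ablations()].
#' @param scene an `anatomy_scene`.
#' @param trajectory_set the plan's `trajectory_set`.
#' @param obstacles pre-built [obstacle_set()] (built on the fly if `NULL`).
#' @param weights a [score_weights()] (for the safety distance in `D`).
#' @param distance_includes_bones include bone surfaces in `d_min_mm`/`D`.
#' @param with_profile also compute `d_avg_mm`, the mean clearance over all
#'   trajectory samples (slower; off during optimization).
#' @return object of class `plan_metrics`.
#' @export
coverage_metrics <- function(ablation_mask, scene, trajectory_set,
                             obstacles = NULL, weights = score_weights(),
                             distance_includes_bones = FALSE,
                             with_profile = FALSE) {
  lab <- scene$labels
  tm <- lab == scene_labels[["tumor"]] | lab == scene_labels[["margin"]]
  tu <- lab == scene_labels[["tumor"]]
  n_abl <- sum(ablation_mask)
  n_tm <- sum(tm)
  M <- if (n_tm > 0) sum(ablation_mask & tm) / n_tm else 0
  tumor_cov <- if (sum(tu) > 0) sum(ablation_mask & tu) / sum(tu) else 0
  H <- if (n_abl > 0) sum(ablation_mask & !tm) / n_abl else 0

  if (is.null(obstacles)) obstacles <- obstacle_set(scene, include_bones = TRUE)
  polys <- c(needle_polylines(trajectory_set), catheter_segments(trajectory_set))
  r <- needle_radius(trajectory_set$needle_spec)
  d_min <- min_surface_distance(polys, obstacles, r,
                                include_bones = distance_includes_bones)
  d_avg <- NA_real_
  if (with_profile) {
    prof <- min_surface_distance(polys, obstacles, r,
                                 include_bones = distance_includes_bones,
                                 per_point = TRUE)
    d_avg <- mean(prof[is.finite(prof)])
  }
  D <- distance_penalty(d_min, weights$safety_distance_mm)
  structure(list(
    M = M,
    tumor_coverage = tumor_cov,
    H = H,
    efficiency = 1 - H,
    N = trajectory_set$config$n_ablations,
    n_ablations_total = n_ablation_tips(trajectory_set),
    n_insertions = 1L,
    d_min_mm = d_min,
    d_avg_mm = d_avg,
    D = D,
    ablated_voxels = n_abl,
    target_voxels = n_tm,
    feasible = NA,
    violations = character(0)
  ), class = "plan_metrics")
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat(sprintf(
    "plan metrics: M=%.3f tumor=%.3f H=%.3f eff=%.3f N=%d (total %d) d_min=%.2f mm D=%.3f\n",
    x$M, x$tumor_coverage, x$H, x$efficiency, x$N, x$n_ablations_total,
    x$d_min_mm, x$D))
  invisible(x)
}
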