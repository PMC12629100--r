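#' Plan score weights
#'
#' Weights of the scalarized plan score
#' `Score = M - w1*N - w2*H - w3*D`: a per-ablation penalty, the
#' healthy-tissue weight, and the distance-penalty weight, plus the safety
#' distance below which clearance starts being penalized. The defaults
#' (0.05, 0.2, 0.5 and 5 mm) were elicited from surgical preference so that a
#' score near 1 means near-complete coverage with all soft constraints
#' respected.
#'
#' @param w1 per-ablation penalty weight.
#' @param w2 healthy-tissue (H) weight.
#' @param w3 distance-penalty (D) weight.
#' @param safety_distance_mm clearance below which D grows linearly to 1.
#' @export
score_weights <- function(w1 = 0.05, w2 = 0.2, w3 = 0.5,
                          safety_distance_mm = 5) {
  stopifnot(w1 >= 0, w2 >= 0, w3 >= 0, safety_distance_mm > 0)
  structure(list(w1 = w1, w2 = w2, w3 = w3,
                 safety_distance_mm = safety_distance_mm),
            class = "score_weights")
}

#' Distance penalty
#'
#' `D = max((s - d) / s, 0)`: 1 at contact, 0 at or beyond the safety
#' distance `s`, linear in between. `d` is the minimum needle/catheter
#' clearance (needle radius already subtracted); `Inf` (no obstacles) gives 0.
#'
#' @param d_mm minimum clearance in mm (>= 0, or `Inf`).
#' @param safety_distance_mm safety distance `s` (> 0).
#' @export
distance_penalty <- function(d_mm, safety_distance_mm = 5) {
  if (safety_distance_mm <= 0) stop("safety_distance_mm must be > 0")
  d <- pmax(d_mm, 0)
  out <- pmax((safety_distance_mm - d) / safety_distance_mm, 0)
  out[is.infinite(d)] <- 0
  out
}

#' Scalarized plan score
#'
#' `Score = M - w1*N - w2*H - w3*D` where `M` is the covered fraction of the
#' tumor-plus-margin volume, `N` the number of peritumoral ablations, `H` the
#' healthy-tissue fraction of the ablated volume and `D` the distance
#' penalty. May be negative.
#'
#' @param metrics a `plan_metrics` (or any list with `M`, `N`, `H`, `D`).
#' @param weights a [score_weights()].
#' @export
compute_score <- function(metrics, weights = score_weights()) {
  metrics$M - weights$w1 * metrics$N - weights$w2 * metrics$H -
    weights$w3 * metrics$D
}

#' Hard-constraint feasibility of a trajectory set
#'
#' A plan is feasible iff:
#' \enumerate{
#'   \item no needle polyline point, thickened by the needle radius,
#'     intersects an obstacle (vessel, bone, other risky structure);
#'   \item every flexure-joint position of every unlocked branch lies inside
#'     the liver;
#'   \item every catheter tip and catheter segment stays inside the liver
#'     (the catheter may cross the tumor and margin);
#'   \item the needle itself never touches the tumor (no-touch rule);
#'   \item the flexion depth does not exceed the entry's distance to the
#'     margin surface (the curved tip must start before the target).
#' }
#'
#' @param trajectory_set a `trajectory_set`.
#' @param scene an `anatomy_scene`.
#' @param needle_spec an [arc_needle_spec()]; defaults to the one stored in
#'   the trajectory set.
#' @param obstacles pre-built [obstacle_set()] with bones (built if `NULL`).
#' @param allow_margin_traversal needle may cross the margin shell (default
#'   `TRUE`; only direct tumor contact is forbidden).
#' @return list with `feasible` (logical) and `violations` (character).
#' @export
check_feasibility <- function(trajectory_set, scene,
                              needle_spec = trajectory_set$needle_spec,
                              obstacles = NULL,
                              allow_margin_traversal = TRUE) {
  ts <- trajectory_set
  violations <- ts$violations
  r <- needle_radius(needle_spec)
  if (is.null(obstacles)) obstacles <- obstacle_set(scene, include_bones = TRUE)

  needle_pts <- do.call(rbind, lapply(needle_polylines(ts),
                                      resample_polyline, step_mm = 1))
  lab <- labels_at(scene, needle_pts)

  # (a) obstacle intersection: containment in an obstacle voxel, or surface
  # closer than the needle radius
  obstacle_codes <- scene_labels[obstacle_label_names]
  hit <- lab %in% obstacle_codes
  if (any(hit)) {
    nm <- names(scene_labels)[match(unique(lab[hit]), scene_labels)]
    violations <- c(violations, paste0("obstacle: needle inside ", nm))
  } else if (nrow(obstacles$points) > 0) {
    d <- min_surface_distance(needle_pts, obstacles, needle_radius_mm = 0,
                              include_bones = TRUE)
    if (d < r) violations <- c(violations, "obstacle: clearance below needle radius")
  }

  # (d) no-touch: the needle must not enter the tumor (nor the margin if
  # margin traversal is disallowed)
  if (any(lab == scene_labels[["tumor"]])) {
    violations <- c(violations, "no-touch: needle enters the tumor")
  }
  if (!allow_margin_traversal && any(lab == scene_labels[["margin"]])) {
    violations <- c(violations, "no-touch: needle enters the margin")
  }

  # (b) unlocked joints inside the liver (margin/tumor voxels count as liver
  # parenchyma; tumor contact is already caught by the no-touch rule)
  liverish <- liverish_labels()
  joints <- do.call(rbind, lapply(ts$branches, function(b) b$joints))
  jl <- labels_at(scene, joints)
  if (any(!(jl %in% liverish))) {
    violations <- c(violations, "joints: unlocked joint outside the liver")
  }

  # (c) catheter tips and segments inside the liver
  cath_pts <- do.call(rbind, lapply(catheter_segments(ts),
                                    resample_polyline, step_mm = 1))
  cl <- labels_at(scene, cath_pts)
  if (any(!(cl %in% liverish))) {
    violations <- c(violations, "catheter: deployed outside the liver")
  }

  # (e) flexion point must precede the margin surface
  if (!is.null(ts$entries_dist_to_margin)) {
    if (ts$config$flexion_depth_mm > ts$entries_dist_to_margin) {
      violations <- c(violations, "flexion: depth beyond the margin surface")
    }
  }

  list(feasible = length(violations) == 0, violations = violations)
}
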