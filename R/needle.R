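#' Steerable-needle geometry specification
#'
#' Geometry of the passive steerable needle: a rigid hollow shaft and an
#' articulated beveled tip whose flexure joints, when unlocked, each bend by a
#' fixed angle so the tip follows a predictable arc. Defaults match the
#' characterized device: 2.8 mm diameter, five joints bending up to 6 degrees
#' each, 3.5 mm axial joint spacing, 5 mm beveled distal section.
#'
#' @param diameter_mm shaft diameter.
#' @param n_joints number of flexure joints.
#' @param joint_max_bend_deg maximal bend per joint (all joints are released
#'   at once at maximal bend in this planner).
#' @param joint_spacing_mm axial spacing between consecutive joints.
#' @param distal_length_mm beveled distal section beyond the last joint.
#' @return object of class `arc_needle_spec`.
#' @export
arc_needle_spec <- function(diameter_mm = 2.8, n_joints = 5,
                            joint_max_bend_deg = 6, joint_spacing_mm = 3.5,
                            distal_length_mm = 5) {
  stopifnot(diameter_mm > 0, n_joints >= 1, joint_max_bend_deg >= 0,
            joint_spacing_mm > 0, distal_length_mm > 0)
  structure(list(diameter_mm = diameter_mm,
                 n_joints = as.integer(n_joints),
                 joint_max_bend_deg = joint_max_bend_deg,
                 joint_spacing_mm = joint_spacing_mm,
                 distal_length_mm = distal_length_mm),
            class = "arc_needle_spec")
}

needle_radius <- function(spec) spec$diameter_mm / 2

# Total tip arc length: first joint sits at the flexion point, so there are
# n_joints - 1 inter-joint gaps plus the distal section (19 mm with defaults).
tip_arc_length <- function(spec) {
  (spec$n_joints - 1) * spec$joint_spacing_mm + spec$distal_length_mm
}

#' A candidate planning configuration
#'
#' The four planning variables: a skin entry point (index into the
#' preprocessed admissible list), the number of peritumoral ablations N in
#' 1..8, the flexion depth (mm from the skin entry to the point where all
#' joints are unlocked), and the rotational shift of the first bending plane
#' within `[0, 2*pi/N]`; plus the run variant adding proximal and/or distal
#' in-tumor ablations.
#'
#' @param entry_index 1-based index into an entry point set.
#' @param n_ablations integer in 1..8.
#' @param flexion_depth_mm depth of the shared flexion point.
#' @param rotation_shift_rad first bending-plane angle, in `[0, 2*pi/N]`.
#' @param variant one of `"none"`, `"prox"`, `"dist"`, `"both"`.
#' @export
planning_configuration <- function(entry_index, n_ablations, flexion_depth_mm,
                                   rotation_shift_rad = 0, variant = "none") {
  stopifnot(n_ablations >= 1, n_ablations <= 8,
            rotation_shift_rad >= -1e-12,
            rotation_shift_rad <= 2 * pi / n_ablations + 1e-9)
  variant <- match.arg(variant, c("none", "prox", "dist", "both"))
  structure(list(entry_index = as.integer(entry_index),
                 n_ablations = as.integer(n_ablations),
                 flexion_depth_mm = flexion_depth_mm,
                 rotation_shift_rad = rotation_shift_rad,
                 variant = variant),
            class = "planning_configuration")
}

#' Build one curved tip branch
#'
#' Piecewise-linear arc of the unlocked tip: the first joint bends at the
#' flexion point, each subsequent joint after one `joint_spacing_mm` segment,
#' and the beveled distal section extends `distal_length_mm` beyond the last
#' joint. After each joint the tangent rotates by `joint_max_bend_deg` within
#' the plane spanned by the shaft direction and the bending direction (the
#' reference normal rotated about the shaft by `plane_angle`).
#'
#' @param flexion_point world point where the joints unlock.
#' @param shaft_dir unit insertion direction of the straight shaft.
#' @param plane_angle bending-plane angle in radians.
#' @param needle_spec an [arc_needle_spec()].
#' @param resample_step_mm resampling step for the returned polyline (<= 1 mm);
#'   `NA` returns the raw joint vertices.
#' @return list with `polyline` (m x 3), `joints` (joint positions), `tip`,
#'   `final_tangent`.
#' @export
build_curved_tip <- function(flexion_point, shaft_dir, plane_angle, needle_spec,
                             resample_step_mm = 1) {
  t_dir <- unit_vector(shaft_dir)
  bend_dir <- rotate_about_axis(reference_normal(t_dir), t_dir, plane_angle)
  axis <- pracma_cross(t_dir, bend_dir)     # rotation axis of the bending plane
  theta <- needle_spec$joint_max_bend_deg * pi / 180
  pts <- matrix(flexion_point, 1, 3)
  p <- flexion_point
  tau <- t_dir
  for (j in seq_len(needle_spec$n_joints)) {
    tau <- rotate_about_axis(tau, axis, theta)
    step <- if (j < needle_spec$n_joints) needle_spec$joint_spacing_mm else
      needle_spec$distal_length_mm
    p <- p + tau * step
    pts <- rbind(pts, p)
  }
  poly <- if (is.na(resample_step_mm)) pts else
    resample_polyline(pts, resample_step_mm)
  list(polyline = poly,
       joints = pts[seq_len(needle_spec$n_joints), , drop = FALSE],
       tip = p,
       final_tangent = tau,
       plane_angle = plane_angle)
}

# cross product (named after its pracma equivalent, kept dependency-free)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the full trajectory set of a planning configuration
#'
#' One shared straight segment from the skin entry to the flexion point, then
#' N curved branches at bending-plane angles `rotation_shift + 2*pi*k/N`
#' (k = 0..N-1). Each branch carries a catheter extended along the branch's
#' final tangent to place the ablation center; the extension defaults to the
#' distance from the needle tip to the tumor-centroid depth plane, clamped to
#' `[0, 20]` mm and shortened if it would leave the liver. For variants
#' `prox`/`dist`/`both`, additional catheter tips are placed on the straight
#' axis inside the tumor by [place_internal_ablations()].
#'
#' @param config a [planning_configuration()].
#' @param entries an entry point set from [generate_entry_candidates()].
#' @param scene an `anatomy_scene`.
#' @param needle_spec an [arc_needle_spec()].
#' @param catheter_max_extension_mm clamp for the catheter extension rule.
#' @return object of class `trajectory_set`.
#' @export
build_plan_trajectories <- function(config, entries, scene, needle_spec,
                                    catheter_max_extension_mm = 20) {
  stopifnot(inherits(config, "planning_configuration"),
            config$entry_index >= 1, config$entry_index <= nrow(entries$points))
  entry <- entries$points[config$entry_index, ]
  dir <- entries$directions[config$entry_index, ]
  flexion <- entry + dir * config$flexion_depth_mm
  straight <- resample_polyline(rbind(entry, flexion), 1)

  centroid <- entries$tumor_centroid
  n <- config$n_ablations
  angles <- config$rotation_shift_rad + 2 * pi * (seq_len(n) - 1) / n
  liverish <- liverish_labels()
  branches <- lapply(angles, function(a) {
    br <- build_curved_tip(flexion, dir, a, needle_spec)
    # catheter: extend the final tangent toward the tumor-centroid depth plane
    ext <- sum((centroid - br$tip) * dir)
    ext <- min(max(ext, 0), catheter_max_extension_mm)
    tip_at <- function(e) br$tip + br$final_tangent * e
    # shorten until the catheter tip stays inside the liver (incl. tumor/margin)
    while (ext > 0 &&
           !(labels_at(scene, rbind(tip_at(ext)))[1] %in% liverish)) {
      ext <- max(ext - 1, 0)
    }
    br$catheter_tip <- tip_at(ext)
    br$catheter_axis <- br$final_tangent
    br$catheter_extension_mm <- ext
    br
  })

  tips <- do.call(rbind, lapply(branches, function(b) b$catheter_tip))
  axes <- do.call(rbind, lapply(branches, function(b) b$catheter_axis))
  ts <- structure(list(
    entry = entry,
    shaft_dir = dir,
    flexion_point = flexion,
    straight = straight,
    branches = branches,
    catheter_tips = tips,
    catheter_axes = axes,
    tip_kind = rep("branch", n),
    config = config,
    needle_spec = needle_spec,
    violations = character(0),
    entries_dist_to_margin = entries$dist_to_margin[config$entry_index],
    resample_step_mm = 1
  ), class = "trajectory_set")
  if (config$variant != "none") {
    ts <- place_internal_ablations(ts, scene, config$variant)
  }
  ts
}

#' Number of catheter tips (= simulated ablations) in a trajectory set
#' @param ts a `trajectory_set`.
#' @export
n_ablation_tips <- function(ts) nrow(ts$catheter_tips)

# All needle polylines (straight shaft + curved branches); the needle itself,
# subject to the no-touch rule.
needle_polylines <- function(ts) {
  c(list(ts$straight), lapply(ts$branches, function(b) b$polyline))
}

# Catheter segments: from each branch tip (or the flexion point, for internal
# ablations on the straight axis) to the catheter tip.
catheter_segments <- function(ts) {
  segs <- list()
  k <- 0
  for (b in ts$branches) {
    k <- k + 1
    segs[[k]] <- rbind(b$tip, b$catheter_tip)
  }
  if (!is.null(ts$internal_tips) && nrow(ts$internal_tips) > 0) {
    for (i in seq_len(nrow(ts$internal_tips))) {
      k <- k + 1
      segs[[k]] <- rbind(ts$flexion_point, ts$internal_tips[i, ])
    }
  }
  segs
}
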