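#' Generate the admissible skin entry points
#'
#' Evaluates every sampled skin surface point against the admissibility
#' filters and returns the surviving candidates in a deterministic order:
#' \enumerate{
#'   \item the straight path from the point toward the tumor centroid,
#'     truncated at the margin surface and thickened by the needle radius,
#'     must be free of obstacle voxels (vessel, bone, other risky);
#'   \item the point must not lie on the patient's posterior side
#'     (`dot(skin normal, back_direction) <= 0`);
#'   \item the path must not cross the operating-table plane;
#'   \item the insertion angle relative to the liver-surface inward normal at
#'     the liver entry point must not exceed `max_angle_deg` (default 30).
#' }
#' Candidates are sorted by (polar angle, azimuth) of the entry position
#' around the tumor centroid, so neighboring indices are spatially adjacent —
#' which makes swarm velocities on the entry-index dimension meaningful.
#'
#' @param scene an `anatomy_scene` with tumor and margin labels.
#' @param needle_spec an [arc_needle_spec()] (for the thickening radius).
#' @param max_angle_deg maximal liver-surface incidence angle.
#' @param thicken_by_radius thicken the admissibility ray by the needle
#'   radius when probing obstacle voxels (default `TRUE`).
#' @return object of class `entry_point_set`: `points`, `normals`,
#'   `directions` (n x 3 matrices), `dist_to_margin`, `dist_to_skin_surface`,
#'   `tumor_centroid`, `ordering_key`.
#' @export
generate_entry_candidates <- function(scene, needle_spec = arc_needle_spec(),
                                      max_angle_deg = 30,
                                      thicken_by_radius = TRUE) {
  if (!any(scene$labels == scene_labels[["tumor"]])) stop("empty tumor")
  centroid <- label_centroid(scene, "tumor")
  P <- scene$skin_points
  Nrm <- scene$skin_normals
  if (is.null(P) || nrow(P) == 0) stop("scene has no skin surface samples")

  # (b) posterior exclusion
  keep <- drop(Nrm %*% scene$back_direction) <= 0
  P <- P[keep, , drop = FALSE]; Nrm <- Nrm[keep, , drop = FALSE]
  if (nrow(P) == 0) stop("no admissible entry point")

  dirs <- sweep(-P, 2, centroid, "+")
  lens <- sqrt(rowSums(dirs^2))
  dirs <- dirs / lens

  # (c) table plane: the path must stay on the patient side of the table
  tp <- scene$table_plane
  h0 <- drop(sweep(P, 2, tp$point, "-") %*% tp$normal)
  h1 <- drop((matrix(centroid, nrow(P), 3, byrow = TRUE) -
                matrix(tp$point, nrow(P), 3, byrow = TRUE)) %*% tp$normal)
  keep <- h0 >= 0 & h1 >= 0
  P <- P[keep, , drop = FALSE]; Nrm <- Nrm[keep, , drop = FALSE]
  dirs <- dirs[keep, , drop = FALSE]; lens <- lens[keep]
  if (nrow(P) == 0) stop("no admissible entry point")

  # walk each ray at 1 mm steps, recording first margin/liver hits and any
  # obstacle hit before the margin surface
  r <- if (thicken_by_radius) needle_radius(needle_spec) else 0
  res <- probe_rays(scene, P, dirs, lens, r)
  ok <- !res$blocked & is.finite(res$t_margin)

  # (d) liver incidence angle
  ang_ok <- rep(FALSE, nrow(P))
  has_liver <- is.finite(res$t_liver)
  if (any(ok & has_liver)) {
    sel <- which(ok & has_liver)
    entry_pts <- P[sel, , drop = FALSE] + dirs[sel, , drop = FALSE] * res$t_liver[sel]
    n_in <- liver_inward_normals(scene, entry_pts)
    cosang <- rowSums(dirs[sel, , drop = FALSE] * n_in)
    ang_ok[sel] <- cosang >= cos(max_angle_deg * pi / 180)
  }
  keep <- ok & ang_ok
  if (!any(keep)) stop("no admissible entry point")

  P <- P[keep, , drop = FALSE]; Nrm <- Nrm[keep, , drop = FALSE]
  dirs <- dirs[keep, , drop = FALSE]
  t_margin <- res$t_margin[keep]

  # deterministic ordering: polar angle then azimuth around the centroid
  rel <- sweep(P, 2, centroid, "-")
  rho <- sqrt(rowSums(rel^2))
  polar <- acos(pmin(pmax(rel[, 3] / pmax(rho, 1e-12), -1), 1))
  azim <- atan2(rel[, 2], rel[, 1])
  ord <- order(round(polar, 9), round(azim, 9), rel[, 1], rel[, 2], rel[, 3],
               method = "radix")

  structure(list(
    points = P[ord, , drop = FALSE],
    normals = Nrm[ord, , drop = FALSE],
    directions = dirs[ord, , drop = FALSE],
    dist_to_margin = t_margin[ord],
    tumor_centroid = centroid,
    max_angle_deg = max_angle_deg,
    ordering_key = "polar angle, then azimuth, around the tumor centroid"
  ), class = "entry_point_set")
}

#' @export
print.entry_point_set <- function(x, ...) {
  cat(sprintf("entry_point_set: %d admissible skin entry points (<= %g deg)\n",
              nrow(x$points), x$max_angle_deg))
  invisible(x)
}

# March rays from P along dirs (unit), 1 mm steps, up to each ray's length.
# Returns first parameter t of margin surface and liver surface, and whether
# an obstacle voxel was probed before the margin (with +/- r lateral probes).
probe_rays <- function(scene, P, dirs, lens, r) {
  n <- nrow(P)
  t_margin <- rep(Inf, n)
  t_liver <- rep(Inf, n)
  blocked <- rep(FALSE, n)
  obstacle_codes <- scene_labels[obstacle_label_names]
  margin_code <- scene_labels[["margin"]]
  tumor_code <- scene_labels[["tumor"]]
  liver_codes <- liverish_labels()

  # lateral probe frame per ray
  if (r > 0) {
    u <- t(apply(dirs, 1, reference_normal))
    v <- cbind(dirs[, 2] * u[, 3] - dirs[, 3] * u[, 2],
               dirs[, 3] * u[, 1] - dirs[, 1] * u[, 3],
               dirs[, 1] * u[, 2] - dirs[, 2] * u[, 1])
  }
  alive <- seq_len(n)
  t_step <- 1
  t <- 0
  max_t <- max(lens)
  while (length(alive) > 0 && t <= max_t) {
    pts <- P[alive, , drop = FALSE] + dirs[alive, , drop = FALSE] * t
    lab <- labels_at(scene, pts)
    if (r > 0) {
      for (s in list(c(r, 0), c(-r, 0), c(0, r), c(0, -r))) {
        side <- pts + u[alive, , drop = FALSE] * s[1] + v[alive, , drop = FALSE] * s[2]
        lab_s <- labels_at(scene, side)
        hit <- lab_s %in% obstacle_codes
        lab[hit & !(lab %in% obstacle_codes)] <- lab_s[hit & !(lab %in% obstacle_codes)]
      }
    }
    first_liver <- lab %in% liver_codes & !is.finite(t_liver[alive])
    t_liver[alive[first_liver]] <- t
    obst <- lab %in% obstacle_codes
    blocked[alive[obst]] <- TRUE
    reached <- lab == margin_code | lab == tumor_code
    t_margin[alive[reached & !obst]] <- t
    drop_idx <- obst | reached | t >= lens[alive]
    alive <- alive[!drop_idx]
    t <- t + t_step
  }
  list(t_margin = t_margin, t_liver = t_liver, blocked = blocked)
}

# Inward liver-surface normals at world points, estimated from the local
# distribution of liver voxels in a 5^3 neighborhood (mask-based; no mesh).
liver_inward_normals <- function(scene, pts) {
  liver_codes <- liverish_labels()
  offs <- as.matrix(expand.grid(dx = -2:2, dy = -2:2, dz = -2:2))
  offs_mm <- sweep(offs, 2, scene$voxel_size, "*")
  acc <- matrix(0, nrow(pts), 3)
  for (k in seq_len(nrow(offs))) {
    probe <- sweep(pts, 2, offs_mm[k, ], "+")
    inside <- labels_at(scene, probe) %in% liver_codes
    acc <- acc + outer(as.numeric(inside), offs_mm[k, ])
  }
  nrm <- sqrt(rowSums(acc^2))
  nrm[nrm < 1e-9] <- 1
  acc / nrm
}
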