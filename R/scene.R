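#' Label codes used in anatomy label grids
#'
#' Integer codes for the structures a planning scene distinguishes. The margin
#' label is produced by [build_margin()]; vessel, bone and `other_risky` are
#' obstacle structures.
#' @export
scene_labels <- c(
  background  = 0L,
  skin        = 1L,   # whole soft-tissue body, bounded by the skin surface
  liver       = 2L,
  tumor       = 3L,
  margin      = 4L,
  vessel      = 5L,
  bone        = 6L,
  other_risky = 7L
)

obstacle_label_names <- c("vessel", "bone", "other_risky")

# Labels whose voxels count as "inside the liver" for the needle shaft and
# joints (margin/tumor voxels were liver before relabeling).
liverish_labels <- function() unname(scene_labels[c("liver", "margin", "tumor")])

#' Construct an anatomy scene
#'
#' The planning environment: an integer label grid in voxel space plus the
#' world geometry every planner component queries (skin surface samples with
#' outward normals, operating-table plane, posterior direction).
#'
#' @param label_grid 3D integer array with values from [scene_labels].
#' @param voxel_size_mm length-3 positive numeric, mm per voxel along each axis.
#' @param origin_mm world coordinates of the center of voxel `[1,1,1]`.
#' @param table_plane list with `point` and `normal` (normal pointing from the
#'   table into the patient).
#' @param back_direction unit vector toward the patient's posterior side.
#' @param skin_points,skin_normals optional n x 3 matrices; computed from the
#'   grid when omitted.
#' @return object of class `anatomy_scene`.
#' @export
anatomy_scene <- function(label_grid, voxel_size_mm,
                          origin_mm = c(0, 0, 0),
                          table_plane = NULL,
                          back_direction = c(0, -1, 0),
                          skin_points = NULL, skin_normals = NULL) {
  stopifnot(length(dim(label_grid)) == 3, length(voxel_size_mm) == 3,
            all(voxel_size_mm > 0))
  storage.mode(label_grid) <- "integer"
  if (is.null(table_plane)) {
    table_plane <- list(point = origin_mm - c(0, 5, 0), normal = c(0, 1, 0))
  }
  scene <- structure(list(
    labels = label_grid,
    voxel_size = as.numeric(voxel_size_mm),
    origin = as.numeric(origin_mm),
    table_plane = table_plane,
    back_direction = unit_vector(back_direction),
    skin_points = skin_points,
    skin_normals = skin_normals,
    margin_clipped_fraction = NA_real_
  ), class = "anatomy_scene")
  if (is.null(skin_points)) {
    surf <- mask_surface_points(scene, scene$labels != scene_labels[["background"]])
    scene$skin_points <- surf$points
    scene$skin_normals <- surf$normals
  }
  scene
}

#' @export
print.anatomy_scene <- function(x, ...) {
  dims <- dim(x$labels)
  counts <- table(factor(x$labels, levels = scene_labels,
                         labels = names(scene_labels)))
  cat(sprintf("anatomy_scene: %d x %d x %d voxels at %.2g x %.2g x %.2g mm\n",
              dims[1], dims[2], dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat("voxel counts:\n")
  print(counts[counts > 0])
  invisible(x)
}

# --- coordinate transforms --------------------------------------------------

#' Convert 1-based voxel indices to world mm
#' @param scene an `anatomy_scene`.
#' @param idx n x 3 matrix of voxel indices.
#' @export
voxel_to_world <- function(scene, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx - 1, 2, scene$voxel_size, "*"), 2, scene$origin, "+")
}

#' Convert world mm to (fractional) 1-based voxel indices
#' @inheritParams voxel_to_world
#' @param pts n x 3 matrix of world points.
#' @export
world_to_voxel <- function(scene, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, scene$origin, "-"), 2, scene$voxel_size, "/") + 1
}

#' Labels at world points
#'
#' Nearest-voxel label lookup; points outside the grid return background.
#' @inheritParams world_to_voxel
#' @return integer vector of labels.
#' @export
labels_at <- function(scene, pts) {
  v <- round(world_to_voxel(scene, pts))
  dims <- dim(scene$labels)
  ok <- v[, 1] >= 1 & v[, 1] <= dims[1] &
        v[, 2] >= 1 & v[, 2] <= dims[2] &
        v[, 3] >= 1 & v[, 3] <= dims[3]
  out <- rep(scene_labels[["background"]], nrow(v))
  if (any(ok)) {
    out[ok] <- scene$labels[cbind(v[ok, 1], v[ok, 2], v[ok, 3])]
  }
  out
}

#' World coordinates of the centers of masked voxels
#' @param scene an `anatomy_scene`.
#' @param mask logical array on the scene grid.
#' @export
mask_voxel_centers <- function(scene, mask) {
  idx <- which(mask, arr.ind = TRUE)
  voxel_to_world(scene, idx)
}

#' Centroid of a labeled structure in world mm
#' @param scene an `anatomy_scene`.
#' @param label_name a name from [scene_labels].
#' @export
label_centroid <- function(scene, label_name) {
  mask <- scene$labels == scene_labels[[label_name]]
  if (!any(mask)) stop(sprintf("no '%s' voxels in scene", label_name))
  colMeans(mask_voxel_centers(scene, mask))
}

# --- surface extraction -----------------------------------------------------

# Boundary voxels of a mask: TRUE voxels with at least one 6-neighbor FALSE
# (or lying on the grid border).
mask_boundary <- function(mask) {
  dims <- dim(mask)
  interior <- array(TRUE, dims)
  shift_and <- function(m, ax, by) {
    out <- array(FALSE, dims)
    src <- dst <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    n <- dims[ax]
    if (by == 1L) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
    else { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(1L, -1L)) {
    interior <- interior & shift_and(mask, ax, by)
  }
  mask & !interior
}

# Sampled surface points + outward normals for a mask. Boundary voxel centers
# give positions; normals are the local mean direction toward non-mask voxels
# within a 5^3 neighborhood (deterministic, mask-based, no mesh needed).
mask_surface_points <- function(scene, mask) {
  bnd <- mask_boundary(mask)
  idx <- which(bnd, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(points = matrix(0, 0, 3), normals = matrix(0, 0, 3)))
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -2:2, dy = -2:2, dz = -2:2))
  offs <- offs[rowSums(offs^2) > 0, , drop = FALSE]
  acc <- matrix(0, nrow(idx), 3)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ni <- sweep(idx, 2, o, "+")
    ok <- ni[, 1] >= 1 & ni[, 1] <= dims[1] &
          ni[, 2] >= 1 & ni[, 2] <= dims[2] &
          ni[, 3] >= 1 & ni[, 3] <= dims[3]
    outside <- !ok
    outside[ok] <- !mask[ni[ok, , drop = FALSE]]
    w <- outside / max(vec_norm(o), 1)
    acc <- acc + outer(w, o * scene$voxel_size)
  }
  nrm <- sqrt(rowSums(acc^2))
  nrm[nrm < 1e-9] <- 1
  list(points = voxel_to_world(scene, idx), normals = acc / nrm)
}

# --- margin construction ----------------------------------------------------

#' Expand the tumor into a safety margin label
#'
#' Builds the peritumoral safety margin (default 10 mm) by labeling every voxel
#' whose center lies within `margin_mm` (world mm, anisotropic-aware) of a
#' tumor voxel center. The margin only overwrites background/liver labels,
#' never vessels or bones, and by default is clipped to the liver.
#'
#' @param scene an `anatomy_scene` (or a bare 3D label array plus `voxel_size_mm`).
#' @param margin_mm margin width in mm (> 0).
#' @param clip_to_liver if `TRUE` (default) margin voxels are only created
#'   inside the liver; the fraction of candidate margin voxels lost to clipping
#'   (or to vessel/bone precedence) is recorded in
#'   `scene$margin_clipped_fraction`.
#' @return the scene with margin voxels relabeled.
#' @export
build_margin <- function(scene, margin_mm = 10, clip_to_liver = TRUE) {
  stopifnot(margin_mm > 0)
  bare <- !inherits(scene, "anatomy_scene")
  if (bare) stop("build_margin expects an anatomy_scene")
  lab <- scene$labels
  tumor <- lab == scene_labels[["tumor"]]
  if (!any(tumor)) stop("empty tumor")
  # previous margin voxels revert to liver so the operation is idempotent
  lab[lab == scene_labels[["margin"]]] <- scene_labels[["liver"]]

  dims <- dim(lab)
  tidx_all <- which(tumor, arr.ind = TRUE)
  # candidates outside the tumor are nearest to a tumor *boundary* voxel, so
  # the distance-to-tumor query only needs the boundary set
  tidx <- which(mask_boundary(tumor), arr.ind = TRUE)
  vs <- scene$voxel_size
  pad <- ceiling(margin_mm / vs) + 1
  lo <- pmax(apply(tidx_all, 2, min) - pad, 1)
  hi <- pmin(apply(tidx_all, 2, max) + pad, dims)
  cand <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  cand_lab <- lab[cand]
  cand <- cand[cand_lab != scene_labels[["tumor"]], , drop = FALSE]

  Tpts <- sweep(tidx, 2, vs, "*")        # world offsets (origin cancels)
  Cpts <- sweep(cand, 2, vs, "*")
  d <- min_cross_distance(Cpts, Tpts, per_point = TRUE)
  shell <- cand[d <= margin_mm, , drop = FALSE]
  if (nrow(shell) > 0) {
    slab <- lab[shell]
    writable <- slab == scene_labels[["liver"]] |
      (!clip_to_liver & slab == scene_labels[["background"]])
    clipped <- 1 - mean(writable)
    lab[shell[writable, , drop = FALSE]] <- scene_labels[["margin"]]
    scene$margin_clipped_fraction <- clipped
  } else {
    scene$margin_clipped_fraction <- 0
  }
  scene$labels <- lab
  scene$margin_mm <- margin_mm
  scene
}

# --- obstacle set and distance queries --------------------------------------

#' Sample obstacle surfaces as a dense point cloud
#'
#' Obstacle structures (vessels, bones, other risky organs) are represented for
#' distance queries by surface samples with nearest-neighbor spacing <= 1 mm:
#' every exposed voxel face on a structure boundary is covered by a sub-grid of
#' face points at most 1 mm apart.
#'
#' @param scene an `anatomy_scene`.
#' @param include_bones keep bone surfaces in the cloud (bones are always hard
#'   obstacles; they are excluded from the *reported* minimum distance by
#'   default, see [min_surface_distance()]).
#' @param max_spacing_mm sampling density bound (default 1 mm).
#' @return object of class `obstacle_set`: `points` (n x 3), `label` (integer
#'   per point), `include_bones`.
#' @export
obstacle_set <- function(scene, include_bones = TRUE, max_spacing_mm = 1) {
  pts <- list(); labs <- list()
  for (nm in obstacle_label_names) {
    if (nm == "bone" && !include_bones) next
    mask <- scene$labels == scene_labels[[nm]]
    if (!any(mask)) next
    p <- sample_mask_faces(scene, mask, max_spacing_mm)
    if (nrow(p) > 0) {
      pts[[nm]] <- p
      labs[[nm]] <- rep(scene_labels[[nm]], nrow(p))
    }
  }
  structure(list(
    points = if (length(pts)) do.call(rbind, pts) else matrix(0, 0, 3),
    label = if (length(labs)) unlist(labs, use.names = FALSE) else integer(0),
    include_bones = include_bones,
    max_spacing_mm = max_spacing_mm
  ), class = "obstacle_set")
}

# Points covering every exposed boundary face of `mask` at <= spacing mm.
sample_mask_faces <- function(scene, mask, spacing) {
  dims <- dim(mask)
  vs <- scene$voxel_size
  out <- list()
  axes <- list(c(2, 3), c(1, 3), c(1, 2))
  for (ax in 1:3) for (sgn in c(-1, 1)) {
    shifted <- array(FALSE, dims)
    n <- dims[ax]
    src <- dst <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    if (sgn == 1) { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    else { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
    shifted[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    # exposed face: mask voxel whose neighbor in direction sgn*ax is outside
    border <- array(FALSE, dims)
    edge <- dst; edge[[ax]] <- if (sgn == 1) n else 1L
    border[edge[[1]], edge[[2]], edge[[3]]] <- TRUE
    faces <- mask & (!shifted | border)
    idx <- which(faces, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    ctr <- voxel_to_world(scene, idx)
    ctr[, ax] <- ctr[, ax] + sgn * vs[ax] / 2
    u <- axes[[ax]][1]; v <- axes[[ax]][2]
    ku <- max(1L, ceiling(vs[u] / spacing))
    kv <- max(1L, ceiling(vs[v] / spacing))
    ou <- (seq_len(ku) - (ku + 1) / 2) * vs[u] / ku
    ov <- (seq_len(kv) - (kv + 1) / 2) * vs[v] / kv
    grid <- expand.grid(ou = ou, ov = ov)
    for (g in seq_len(nrow(grid))) {
      p <- ctr
      p[, u] <- p[, u] + grid$ou[g]
      p[, v] <- p[, v] + grid$ov[g]
      out[[length(out) + 1L]] <- p
    }
  }
  if (length(out)) do.call(rbind, out) else matrix(0, 0, 3)
}

#' Minimum needle-to-obstacle surface distance
#'
#' Minimum over all (trajectory sample, obstacle surface sample) pairs of the
#' Euclidean distance, minus the needle radius, floored at zero. Trajectories
#' are resampled at <= 1 mm; obstacle surfaces are pre-sampled at <= 1 mm by
#' [obstacle_set()].
#'
#' @param polyline an n x 3 matrix, or a list of such matrices (all branches /
#'   catheter segments of a plan).
#' @param obstacles an `obstacle_set`.
#' @param needle_radius_mm radius subtracted from the center-line distance.
#' @param include_bones count bone surfaces; defaults to the obstacle set's
#'   flag. Set `FALSE` for the reported metric (bones excluded).
#' @param per_point return the per-trajectory-sample clearance profile instead
#'   of the scalar minimum.
#' @return distance in mm (`Inf` when the obstacle set is empty).
#' @export
min_surface_distance <- function(polyline, obstacles, needle_radius_mm = 0,
                                 include_bones = obstacles$include_bones,
                                 per_point = FALSE) {
  polys <- if (is.list(polyline)) polyline else list(polyline)
  P <- do.call(rbind, lapply(polys, resample_polyline, step_mm = 1))
  Q <- obstacles$points
  if (!include_bones && nrow(Q) > 0) {
    Q <- Q[obstacles$label != scene_labels[["bone"]], , drop = FALSE]
  }
  if (nrow(Q) == 0) return(if (per_point) rep(Inf, nrow(P)) else Inf)
  if (per_point) {
    d <- min_cross_distance(P, Q, per_point = TRUE)
    return(pmax(d - needle_radius_mm, 0))
  }
  # two-phase exact search: a strided subsample gives an upper bound d0 on the
  # true minimum; only obstacle points within d0 of the trajectory's bounding
  # box can attain the minimum.
  if (nrow(Q) > 3000) {
    stride <- ceiling(nrow(Q) / 1500)
    d0 <- min_cross_distance(P, Q[seq(1, nrow(Q), by = stride), , drop = FALSE])
    lo <- apply(P, 2, min); hi <- apply(P, 2, max)
    keep <- dist_to_aabb(Q, lo, hi) <= d0 + 1e-9
    Q <- Q[keep, , drop = FALSE]
  }
  d <- min_cross_distance(P, Q)
  max(d - needle_radius_mm, 0)
}
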