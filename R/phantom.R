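#' Specification of a synthetic anatomical phantom
#'
#' Geometric stand-in for an abdominal CT segmentation: a superellipsoid body
#' (skin), an ellipsoidal liver, an ellipsoidal tumor with its safety margin,
#' capsule-shaped vessels inside the liver, rib-like bone capsules near the
#' body surface, and a table plane below the body. All coordinates are world
#' mm; the grid is centered on the origin.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_size_mm mm per voxel (scalar or length 3).
#' @param body_semiaxes_mm superellipsoid semi-axes of the body.
#' @param body_exponent superellipsoid exponent (2 = ellipsoid; larger = boxier).
#' @param liver_center_mm,liver_semiaxes_mm liver ellipsoid.
#' @param tumor_center_mm,tumor_semiaxes_mm tumor ellipsoid (volumes in the
#'   75-16900 mm^3 range are representative of clinical lesions).
#' @param n_vessels,vessel_radius_mm number of random intra-hepatic vessel
#'   capsules and their radius range.
#' @param vessel_region optional function(seed-rng) returning fixed vessel
#'   segments; `NULL` places them randomly in the posterior liver half.
#' @param ribs list of rib capsules, each `list(a =, b =, r =)` in world mm;
#'   `NULL` for the default lateral pair.
#' @param bone_shell optional `list(center, radius, thickness, window_dir,
#'   window_half_angle_deg)` adding a spherical bone shell (with an optional
#'   angular window) around `center`; used to block or narrow entry corridors.
#' @param margin_mm safety margin width (default 10).
#' @param seed integer seed controlling vessel placement.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         voxel_size_mm = 1.5,
                         body_semiaxes_mm = c(65, 55, 68),
                         body_exponent = 2.5,
                         liver_center_mm = c(10, 8, 0),
                         liver_semiaxes_mm = c(42, 32, 38),
                         tumor_center_mm = c(10, 12, 0),
                         tumor_semiaxes_mm = c(3, 3, 3),
                         n_vessels = 2,
                         vessel_radius_mm = c(1.5, 3),
                         vessel_region = NULL,
                         ribs = NULL,
                         bone_shell = NULL,
                         margin_mm = 10,
                         seed = 1L) {
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  structure(as.list(environment()), class = "phantom_spec")
}

# ellipsoid / superellipsoid membership for voxel centers X (n x 3)
inside_superellipsoid <- function(X, center, semi, p = 2) {
  u <- abs(sweep(X, 2, center, "-"))
  u <- sweep(u, 2, semi, "/")
  rowSums(u^p) <= 1
}

# capsule membership: distance to segment [a, b] <= r, vectorized over X
inside_capsule <- function(X, a, b, r) {
  ab <- b - a
  len2 <- max(sum(ab * ab), 1e-300)
  t <- pmin(pmax((sweep(X, 2, a, "-") %*% ab) / len2, 0), 1)
  proj <- outer(drop(t), ab) + matrix(a, nrow(X), 3, byrow = TRUE)
  rowSums((X - proj)^2) <= r^2
}

#' Generate a synthetic anatomy scene
#'
#' Rasterizes the phantom's primitives into a label grid with precedence
#' bone > vessel > tumor > margin > liver > skin > background, builds the
#' safety margin via [build_margin()], extracts the skin surface, and attaches
#' the table plane. Deterministic given `spec` and `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return an `anatomy_scene`.
#' @export
generate_phantom <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- as.integer(spec$grid_shape)
  vs <- spec$voxel_size_mm
  extent <- dims * vs
  origin <- -extent / 2 + vs / 2          # grid centered on the world origin
  idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])))
  X <- sweep(sweep(idx - 1, 2, vs, "*"), 2, origin, "+")

  lab <- rep(scene_labels[["background"]], nrow(X))
  body <- inside_superellipsoid(X, c(0, 0, 0), spec$body_semiaxes_mm,
                                spec$body_exponent)
  lab[body] <- scene_labels[["skin"]]
  liver <- inside_superellipsoid(X, spec$liver_center_mm, spec$liver_semiaxes_mm)
  lab[liver] <- scene_labels[["liver"]]
  tumor <- inside_superellipsoid(X, spec$tumor_center_mm, spec$tumor_semiaxes_mm)
  if (any(tumor & !liver)) stop("tumor not strictly inside liver")
  if (!any(tumor)) stop("tumor too small for this voxel size")
  lab[tumor] <- scene_labels[["tumor"]]

  # vessels (inside liver, never overwriting tumor)
  vessels <- spec$vessel_region
  if (is.null(vessels)) {
    vessels <- with_local_seed(seed, {
      lapply(seq_len(spec$n_vessels), function(i) {
        ctr <- spec$liver_center_mm
        semi <- spec$liver_semiaxes_mm * 0.6
        repeat {
          a <- ctr + stats::runif(3, -1, 1) * semi
          b <- ctr + stats::runif(3, -1, 1) * semi
          a[2] <- ctr[2] - abs(a[2] - ctr[2])   # posterior half of the liver
          b[2] <- ctr[2] - abs(b[2] - ctr[2])
          if (vec_norm(b - a) > 15) break
        }
        list(a = a, b = b,
             r = stats::runif(1, spec$vessel_radius_mm[1], spec$vessel_radius_mm[2]))
      })
    })
  }
  for (v in vessels) {
    m <- inside_capsule(X, v$a, v$b, v$r) & liver &
      lab != scene_labels[["tumor"]]
    lab[m] <- scene_labels[["vessel"]]
  }

  # ribs: bone capsules just inside the body surface, outside the liver
  ribs <- spec$ribs
  if (is.null(ribs)) {
    ribs <- list(
      list(a = c(-55, 20, -25), b = c(-45, 40, 25), r = 4),
      list(a = c(55, 20, -25), b = c(62, 35, 25), r = 4)
    )
  }
  for (rb in ribs) {
    m <- inside_capsule(X, rb$a, rb$b, rb$r) & body & !liver
    lab[m] <- scene_labels[["bone"]]
  }

  # optional bone shell with an angular window (corridor control)
  bs <- spec$bone_shell
  if (!is.null(bs)) {
    d <- sweep(X, 2, bs$center, "-")
    r <- sqrt(rowSums(d^2))
    m <- r >= bs$radius & r <= bs$radius + bs$thickness & body & !liver & !tumor
    if (!is.null(bs$window_dir)) {
      wd <- unit_vector(bs$window_dir)
      cosang <- (d %*% wd) / pmax(r, 1e-9)
      m <- m & drop(cosang) < cos(bs$window_half_angle_deg * pi / 180)
    }
    lab[m] <- scene_labels[["bone"]]
  }

  grid <- array(lab, dims)
  table_plane <- list(point = c(0, -spec$body_semiaxes_mm[2] - 5, 0),
                      normal = c(0, 1, 0))
  scene <- anatomy_scene(grid, vs, origin_mm = origin,
                         table_plane = table_plane,
                         back_direction = c(0, -1, 0))
  scene <- build_margin(scene, spec$margin_mm)
  scene$phantom_spec <- spec
  scene
}

#' Named test-suite phantom scenes
#'
#' A fixed roster of scenes exercising qualitatively different planning
#' regimes:
#' \describe{
#'   \item{easy}{small central tumor (3 mm radius), clear anterior window;
#'     constructed so a single default ablation ellipsoid centered inside the
#'     tumor contains the whole tumor-plus-margin.}
#'   \item{narrow}{tumor behind a rib-shell window with a vessel crossing the
#'     only corridor ~2 mm off its axis, forcing sub-5 mm clearances and a
#'     nonzero distance penalty.}
#'   \item{large}{ellipsoidal tumor of ~16,900 mm^3 that no single default
#'     ablation volume can cover.}
#'   \item{blocked}{complete bone shell around the liver: no admissible entry
#'     point exists and the planner must fail cleanly.}
#' }
#'
#' @param voxel_mm voxel size for all scenes (default 1.5 mm; 2 mm keeps
#'   end-to-end runs fast).
#' @param which optional character vector selecting a subset.
#' @return named list of `anatomy_scene` objects.
#' @export
make_test_suite_scenes <- function(voxel_mm = 1.5, which = NULL) {
  n <- function(extent) as.integer(ceiling(extent / voxel_mm))
  specs <- list(
    easy = phantom_spec(
      grid_shape = rep(n(145), 3), voxel_size_mm = voxel_mm,
      tumor_center_mm = c(10, 12, 0), tumor_semiaxes_mm = c(3, 3, 3),
      vessel_region = list(
        list(a = c(-15, -12, -15), b = c(25, -14, 10), r = 2.5),
        list(a = c(0, -10, -20), b = c(30, -8, -18), r = 2)
      ),
      seed = 11L
    ),
    narrow = phantom_spec(
      grid_shape = rep(n(145), 3), voxel_size_mm = voxel_mm,
      tumor_center_mm = c(10, 8, 0), tumor_semiaxes_mm = c(4, 4, 4),
      vessel_region = list(
        # crosses the anterior corridor (axis +y through the tumor) at
        # y = +26 mm, offset 2 mm in x from the corridor axis
        list(a = c(12, 34, -20), b = c(12, 18, 20), r = 1.5)
      ),
      bone_shell = list(center = c(10, 8, 0), radius = 38, thickness = 5,
                        window_dir = c(0, 1, 0), window_half_angle_deg = 11),
      seed = 12L
    ),
    large = phantom_spec(
      grid_shape = rep(n(190), 3), voxel_size_mm = voxel_mm,
      body_semiaxes_mm = c(85, 70, 88),
      liver_center_mm = c(10, 8, 0), liver_semiaxes_mm = c(55, 45, 50),
      tumor_center_mm = c(10, 10, 0), tumor_semiaxes_mm = c(16, 16, 15.7),
      ribs = list(list(a = c(-75, 20, -25), b = c(-65, 45, 25), r = 4)),
      seed = 13L
    ),
    blocked = phantom_spec(
      grid_shape = rep(n(145), 3), voxel_size_mm = voxel_mm,
      tumor_center_mm = c(10, 8, 0), tumor_semiaxes_mm = c(4, 4, 4),
      bone_shell = list(center = c(10, 8, 0), radius = 40, thickness = 6,
                        window_dir = NULL),
      seed = 14L
    )
  )
  if (!is.null(which)) specs <- specs[which]
  lapply(specs, generate_phantom)
}
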