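# Serialization: label volumes (NIfTI via RNifti, minimal ASCII NRRD),
# scene configuration YAML, and plan/metrics JSON.

#' Read a label volume into an anatomy scene
#'
#' Supports NIfTI (`.nii`/`.nii.gz`, through the RNifti package) and the
#' package's ASCII NRRD subset. Integer values are remapped through
#' `label_map`, a named vector `{structure name -> file value}` covering any
#' subset of [scene_labels] names.
#'
#' @param path volume file.
#' @param label_map named integer vector mapping structure names to the
#'   file's label values; defaults to the identity mapping of [scene_labels].
#' @param table_plane,back_direction scene geometry (see [anatomy_scene()]).
#' @return an `anatomy_scene`.
#' @export
read_label_volume <- function(path, label_map = scene_labels,
                              table_plane = NULL,
                              back_direction = c(0, -1, 0)) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    vol <- read_nrrd(path)
    arr <- vol$data; vs <- vol$voxel_size; origin <- vol$origin
  } else {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI requires the RNifti package")
    }
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    vs <- RNifti::pixdim(img)[1:3]
    origin <- unname(RNifti::xform(img)[1:3, 4])  # affine translation (mm)
  }
  out <- array(scene_labels[["background"]], dim(arr))
  for (nm in names(label_map)) {
    if (!nm %in% names(scene_labels)) next
    out[arr == label_map[[nm]]] <- scene_labels[[nm]]
  }
  anatomy_scene(out, vs, origin_mm = origin, table_plane = table_plane,
                back_direction = back_direction)
}

#' Write a 3D array as ASCII NRRD
#'
#' Minimal detached-header-free NRRD writer (text encoding) for derived
#' margin/ablation masks; readable by standard NRRD tools and by
#' [read_nrrd()].
#'
#' @param arr 3D integer/logical array.
#' @param path output file.
#' @param voxel_size_mm spacings written to the header.
#' @param origin_mm world position of the first voxel center.
#' @export
write_nrrd <- function(arr, path, voxel_size_mm = c(1, 1, 1),
                       origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(arr)) == 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    "type: int",
    "dimension: 3",
    sprintf("sizes: %d %d %d", dim(arr)[1], dim(arr)[2], dim(arr)[3]),
    sprintf("spacings: %g %g %g", voxel_size_mm[1], voxel_size_mm[2],
            voxel_size_mm[3]),
    sprintf("axis mins: %g %g %g", origin_mm[1], origin_mm[2], origin_mm[3]),
    "encoding: ascii",
    ""
  ), con)
  writeLines(paste(as.integer(arr), collapse = " "), con)
}

#' Read the ASCII NRRD subset written by [write_nrrd()]
#' @param path NRRD file with `encoding: ascii`.
#' @return list with `data` (3D array), `voxel_size`, `origin`.
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "NRRD")) stop("not a NRRD file")
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("malformed NRRD: missing header terminator")
  header <- lines[2:(blank - 1)]
  get <- function(key, default = NULL) {
    ln <- header[startsWith(header, paste0(key, ":"))]
    if (length(ln) == 0) return(default)
    trimws(sub(paste0(key, ":"), "", ln[1]))
  }
  if (!identical(get("encoding"), "ascii")) {
    stop("only ascii encoding is supported")
  }
  sizes <- as.integer(strsplit(get("sizes"), "\\s+")[[1]])
  spacings <- as.numeric(strsplit(get("spacings", "1 1 1"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("axis mins", "0 0 0"), "\\s+")[[1]])
  vals <- scan(text = paste(lines[(blank + 1):length(lines)], collapse = " "),
               quiet = TRUE)
  stopifnot(length(vals) == prod(sizes))
  list(data = array(as.integer(vals), sizes), voxel_size = spacings,
       origin = origin)
}

#' Export a plan (trajectories + metrics) to JSON
#'
#' Versioned schema, world mm throughout, carrying enough of the
#' configuration to rebuild the trajectories and reproduce the metrics.
#'
#' @param ts a `trajectory_set`.
#' @param metrics optional `plan_metrics`.
#' @param path output JSON file.
#' @param score optional score value.
#' @export
export_plan_json <- function(ts, path, metrics = NULL, score = NULL) {
  plan <- list(
    schema = "arcplan-plan-v1",
    config = unclass(ts$config),
    entry = ts$entry,
    shaft_dir = ts$shaft_dir,
    flexion_point = ts$flexion_point,
    branches = lapply(ts$branches, function(b) list(
      plane_angle = b$plane_angle,
      polyline = b$polyline,
      catheter_tip = b$catheter_tip,
      catheter_extension_mm = b$catheter_extension_mm
    )),
    catheter_tips = ts$catheter_tips,
    tip_kind = ts$tip_kind,
    needle_spec = unclass(ts$needle_spec),
    metrics = if (!is.null(metrics)) unclass(metrics),
    score = score
  )
  jsonlite::write_json(plan, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a plan JSON written by [export_plan_json()]
#' @param path plan file.
#' @return list mirroring the export schema (matrices restored).
#' @export
load_plan_json <- function(path) {
  plan <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(plan$schema, "arcplan-plan-v1")) {
    stop("unsupported plan schema")
  }
  plan$config <- structure(as.list(plan$config),
                           class = "planning_configuration")
  plan$config$entry_index <- as.integer(plan$config$entry_index)
  plan$config$n_ablations <- as.integer(plan$config$n_ablations)
  plan
}

#' Export needle polylines as a Wavefront OBJ line set
#'
#' Visualization aid: straight segment, branches and catheter segments as
#' polylines (`l` elements) in one OBJ file.
#'
#' @param ts a `trajectory_set`.
#' @param path output `.obj` file.
#' @export
export_plan_obj <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  offset <- 0L
  for (poly in c(needle_polylines(ts), catheter_segments(ts))) {
    for (i in seq_len(nrow(poly))) {
      writeLines(sprintf("v %.4f %.4f %.4f", poly[i, 1], poly[i, 2],
                         poly[i, 3]), con)
    }
    writeLines(paste(c("l", offset + seq_len(nrow(poly))), collapse = " "),
               con)
    offset <- offset + nrow(poly)
  }
  invisible(path)
}

#' Write a planner configuration snapshot as YAML
#'
#' A run record: every weight, bound, needle and ablation parameter plus the
#' seed, sufficient to reproduce a deterministic run bit-for-bit.
#'
#' @param path output YAML file.
#' @param needle_spec,abl_params,weights,psam,mc planner components.
#' @param seed integer seed.
#' @param extra named list appended verbatim.
#' @export
write_run_config <- function(path, needle_spec = arc_needle_spec(),
                             abl_params = ablation_params(),
                             weights = score_weights(),
                             psam = psam_params(), mc = mc_config(),
                             seed = 1L, extra = list()) {
  cfg <- c(list(
    schema = "arcplan-config-v1",
    seed = seed,
    needle = unclass(needle_spec),
    ablation = unclass(abl_params),
    weights = unclass(weights),
    psam = unclass(psam),
    mc = unclass(mc)
  ), extra)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a planner configuration snapshot
#' @param path YAML file from [write_run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(
    seed = cfg$seed,
    needle_spec = do.call(arc_needle_spec, cfg$needle[
      names(cfg$needle) %in% names(formals(arc_needle_spec))]),
    abl_params = do.call(ablation_params, cfg$ablation[
      names(cfg$ablation) %in% names(formals(ablation_params))]),
    weights = do.call(score_weights, cfg$weights[
      names(cfg$weights) %in% names(formals(score_weights))]),
    psam = do.call(psam_params, cfg$psam[
      names(cfg$psam) %in% names(formals(psam_params))]),
    mc = do.call(mc_config, cfg$mc[
      names(cfg$mc) %in% names(formals(mc_config))])
  )
}
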