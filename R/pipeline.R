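#' Detect antibodies in a cryo-EM map
#'
#' The full prediction pipeline: read the map (if a path is given), resample
#' it to 2 Angstrom voxels, normalize, run the detection network, apply
#' persistence-diagram non-maximal suppression to the occupancy channel,
#' select components (`thresh` or `num` mode) and decode each selected
#' component's seed cell into a placed pose. Needs nothing beyond the map
#' and a trained model. Detections are reported in the map's physical
#' (Angstrom) frame, honoring the original map origin, so emitted PDBs
#' overlay the input map in visualization tools.
#'
#' @param map A [density_grid()] or a path to an MRC/CCP4 map file.
#' @param model A `unet_model` or a path to a checkpoint file.
#' @param mode `"thresh"` (keep components with lifetime > `tau`; fully
#'   automatic) or `"num"` (keep the top `k`).
#' @param k Number of detections in `num` mode.
#' @param tau Lifetime threshold in `thresh` mode (default 0.2).
#' @param min_occupancy Optional floor on the occupancy score of a detection;
#'   discards low-value artifact peaks and trades recall for precision on
#'   maps that may contain no antibody at all (suggested value 0.5; off by
#'   default).
#' @param voxel Working voxel size (default 2 Angstrom; maps are resampled
#'   to it).
#' @return List of `detection` objects, sorted by decreasing lifetime; each
#'   has `pose` ([ab_pose()]), `occupancy_score`, `lifetime` and
#'   `vhh_probability`.
#' @export
detect_antibodies <- function(map, model, mode = c("thresh", "num"), k = NULL,
                              tau = 0.2, min_occupancy = NULL, voxel = 2) {
  mode <- match.arg(mode)
  if (is.character(map)) map <- read_map(map)
  if (is.character(model)) model <- load_checkpoint(model)
  stopifnot(inherits(map, "density_grid"), inherits(model, "unet_model"))
  grid <- normalize_grid(resample_grid(map, voxel))
  pred <- predict_grid(model, grid)
  occ <- pred$channels[, , , 1]
  comps <- persistence_components(occ)
  sel <- select_detections(comps, mode = mode, k = k, tau = tau)
  out <- list()
  for (r in seq_len(nrow(sel))) {
    ci <- as.integer(sel[r, c("seed_x", "seed_y", "seed_z")])
    pose <- decode_cell(pred, ci)
    det <- structure(list(
      pose = pose,
      occupancy_score = occ[ci[1] + 1, ci[2] + 1, ci[3] + 1],
      lifetime = sel$lifetime[r],
      vhh_probability = pred$channels[ci[1] + 1, ci[2] + 1, ci[3] + 1, 10],
      seed_cell = ci), class = "detection")
    if (!is.null(min_occupancy) && det$occupancy_score < min_occupancy) next
    out[[length(out) + 1]] <- det
  }
  out
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf(
    "<detection> %s at (%s) A, score %.3f, lifetime %.3f, P(vhh) %.3f\n",
    x$pose$ab_class,
    paste(format(x$pose$translation, digits = 4), collapse = ", "),
    x$occupancy_score, x$lifetime, x$vhh_probability))
  invisible(x)
}

#' Write detections as placed templates in PDB format
#'
#' Each detection selects the template of its predicted class (Fab or VHH),
#' transforms its atoms by the detection's pose, and is written as one MODEL
#' block. The occupancy column carries the detection's occupancy score and
#' the B-factor column its persistence lifetime, so downstream tools can
#' rank or filter models. Zero detections yield a valid header-only file.
#'
#' @param detections List of detections from [detect_antibodies()].
#' @param templates Named list with `fab` and `vhh` [ab_template()]s.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_detections_pdb <- function(detections,
                                 templates = list(fab = make_pseudo_template("fab"),
                                                  vhh = make_pseudo_template("vhh")),
                                 path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("REMARK   3 ANTIBODY DETECTIONS PLACED AS RIGID TEMPLATES",
               "REMARK   3 OCCUPANCY = DETECTION SCORE, B-FACTOR = LIFETIME"),
             con)
  for (m in seq_along(detections)) {
    det <- detections[[m]]
    tmpl <- templates[[det$pose$ab_class]]
    if (is.null(tmpl)) stop("no template for class ", det$pose$ab_class)
    xyz <- sweep(tmpl$coords %*% t(det$pose$rotation), 2,
                 -det$pose$translation)
    writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(nrow(xyz))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
        i, substr(tmpl$atom_names[i], 1, 4), "ALA",
        substr(tmpl$chain[i], 1, 1), tmpl$resno[i] %% 10000,
        xyz[i, 1], xyz[i, 2], xyz[i, 3],
        min(det$occupancy_score, 1), min(det$lifetime, 999.99), "C"), con)
    }
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write / read ground-truth poses as JSON
#'
#' Sidecar format for simulated maps: rotation matrices (row-major),
#' translations and classes, so evaluation can run from files.
#'
#' @param poses List of [ab_pose()].
#' @param path JSON file path.
#' @return `path` invisibly (write), or the pose list (read).
#' @export
write_poses_json <- function(poses, path) {
  obj <- lapply(poses, function(p) list(
    rotation = as.numeric(t(p$rotation)),
    translation = p$translation,
    ab_class = p$ab_class))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_poses_json
#' @export
read_poses_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(obj) == 0 || (is.data.frame(obj) && nrow(obj) == 0)) return(list())
  if (is.data.frame(obj)) {
    lapply(seq_len(nrow(obj)), function(i) ab_pose(
      matrix(unlist(obj$rotation[i]), 3, 3, byrow = TRUE),
      unlist(obj$translation[i]),
      ab_class = obj$ab_class[i]))
  } else {
    lapply(obj, function(p) ab_pose(
      matrix(unlist(p$rotation), 3, 3, byrow = TRUE),
      unlist(p$translation), ab_class = p$ab_class))
  }
}

#' Centers of mass of the models in a detections PDB
#'
#' Reads back a PDB written by [write_detections_pdb()] and returns one
#' center of mass per MODEL, for file-based evaluation.
#'
#' @param path PDB file path.
#' @return n x 3 matrix of centers (Angstrom).
#' @export
read_detection_centers <- function(path) {
  lines <- readLines(path)
  centers <- NULL
  cur <- NULL
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (tag == "MODEL ") cur <- NULL
    else if (tag == "ATOM  ")
      cur <- rbind(cur, as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                     substr(ln, 47, 54))))
    else if (tag == "ENDMDL" && !is.null(cur))
      centers <- rbind(centers, colMeans(cur))
  }
  if (is.null(centers)) matrix(0, 0, 3) else centers
}
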