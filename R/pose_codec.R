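#' Antibody pose
#'
#' One antibody's placement as a rigid transform of the template: a proper
#' rotation and a translation (the template center of mass after placement,
#' in map Angstrom coordinates), plus the derived quantities used by the grid
#' encoding: the binding direction `direction = rotation %*% u_z`, the
#' residual in-plane angle `angle`, and — when a grid geometry is attached —
#' the owner cell index `cell_index` (0-based) and the intra-cell offset
#' `local_offset` with `translation == cell_corner + local_offset`.
#'
#' @param rotation 3x3 proper rotation.
#' @param translation Length-3 Angstrom position of the placed template center.
#' @param ab_class `"fab"` or `"vhh"`.
#' @param geometry Optional [grid_geometry()]; if given, the cell
#'   decomposition fields are filled in.
#' @param u_z Template canonical axis (default `c(0, 0, 1)`).
#' @return An object of class `ab_pose`.
#' @export
ab_pose <- function(rotation, translation, ab_class = c("fab", "vhh"),
                    geometry = NULL, u_z = c(0, 0, 1)) {
  ab_class <- match.arg(ab_class)
  check_rotation(rotation)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  dec <- decompose_rotation(rotation, u_z)
  pose <- structure(list(
    rotation = rotation, translation = translation,
    direction = dec$direction, angle = dec$angle,
    cell_index = NULL, local_offset = NULL,
    ab_class = ab_class), class = "ab_pose")
  if (!is.null(geometry)) pose <- attach_cell(pose, geometry)
  pose
}

attach_cell <- function(pose, geometry) {
  rel <- (pose$translation - geometry$origin) / geometry$cell_size
  ci <- as.integer(floor(rel + 1e-12))
  pose$cell_index <- ci
  pose$local_offset <- pose$translation - (geometry$origin + ci * geometry$cell_size)
  pose
}

#' @export
print.ab_pose <- function(x, ...) {
  cat(sprintf("<ab_pose> %s at (%s) A, direction (%s), angle %.3f rad\n",
              x$ab_class,
              paste(format(x$translation, digits = 4), collapse = ", "),
              paste(format(x$direction, digits = 3), collapse = ", "),
              x$angle))
  invisible(x)
}

#' Occupancy-grid geometry
#'
#' Geometry of the coarse detection grid overlaid on a map: cubic cells of
#' fixed physical size (default 8 Angstrom, i.e. 4 input voxels at 2
#' Angstrom), an origin (Angstrom position of the corner of cell
#' `(0, 0, 0)`) and the number of cells per axis.
#'
#' @param dim Integer length-3 number of cells per axis.
#' @param cell_size Cell edge in Angstrom (default 8).
#' @param origin Length-3 Angstrom position of the grid corner.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(dim, cell_size = 8, origin = c(0, 0, 0)) {
  dim <- as.integer(rep_len(dim, 3L))
  stopifnot(all(dim >= 1), cell_size > 0)
  structure(list(dim = dim, cell_size = as.numeric(cell_size),
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "grid_geometry")
}

# Geometry of the prediction/target grid covering a density grid at `stride`
# voxels per cell.
geometry_for_grid <- function(grid, stride = 4L) {
  d <- dim(grid$values)
  grid_geometry(ceiling(d / stride), cell_size = stride * grid$voxel[1],
                origin = grid$origin)
}

#' 10-channel pose grid (target or prediction)
#'
#' Array of shape `(nx, ny, nz, 10)` over grid cells. Channels (R 1-based):
#' 1 occupancy (binary target / sigmoid prediction), 2-4 intra-cell offset
#' `T_loc` (Angstrom from the cell corner), 5-7 binding direction `p`,
#' 8-9 `(cos theta, sin theta)`, 10 VHH class probability. For a ground-truth
#' grid, pose channels are defined only where channel 1 is 1 and are zero
#' elsewhere.
#'
#' @param channels `(nx, ny, nz, 10)` numeric array.
#' @param geometry The [grid_geometry()].
#' @param kind `"target"` or `"prediction"`.
#' @return An object of class `pose_grid`.
#' @export
pose_grid <- function(channels, geometry, kind = c("target", "prediction")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(channels)) == 4, dim(channels)[4] == 10,
            all(dim(channels)[1:3] == geometry$dim))
  structure(list(channels = channels, geometry = geometry, kind = kind),
            class = "pose_grid")
}

#' @export
print.pose_grid <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<pose_grid> (%s) %d x %d x %d cells of %g A, occupancy sum %.3f\n",
              x$kind, d[1], d[2], d[3], x$geometry$cell_size,
              sum(x$channels[, , , 1])))
  invisible(x)
}

#' Encode antibody poses into a ground-truth pose grid
#'
#' Each pose marks its owner cell (the cell containing the placed template's
#' center of mass) with occupancy 1 and writes its intra-cell offset, binding
#' direction, `(cos theta, sin theta)` and VHH indicator into the pose
#' channels of that cell; everything else is zero. Two poses may not own the
#' same cell (at 8 Angstrom cells two antibody centers cannot share a cell).
#'
#' @param poses List of [ab_pose()].
#' @param geometry A [grid_geometry()].
#' @return A ground-truth [pose_grid()] whose occupancy sums to `length(poses)`.
#' @export
encode_poses <- function(poses, geometry) {
  ch <- array(0, c(geometry$dim, 10L))
  seen <- character(0)
  for (pose in poses) {
    pose <- attach_cell(pose, geometry)
    ci <- pose$cell_index
    if (any(ci < 0) || any(ci >= geometry$dim))
      stop("pose translation lies outside the grid extent")
    key <- paste(ci, collapse = ",")
    if (key %in% seen)
      stop("two poses own the same grid cell (", key, "): cannot be encoded")
    seen <- c(seen, key)
    i <- ci + 1L
    ch[i[1], i[2], i[3], 1] <- 1
    ch[i[1], i[2], i[3], 2:4] <- pose$local_offset
    ch[i[1], i[2], i[3], 5:7] <- pose$direction
    ch[i[1], i[2], i[3], 8:9] <- c(cos(pose$angle), sin(pose$angle))
    ch[i[1], i[2], i[3], 10] <- as.numeric(pose$ab_class == "vhh")
  }
  pose_grid(ch, geometry, kind = "target")
}

#' Decode one grid cell into an antibody pose
#'
#' Inverse of the encoding at a single cell: the translation is the cell
#' corner plus the offset channels (clamped into the cell), the direction is
#' the normalized direction channels, the angle is `atan2` of the sine/cosine
#' channels, the class is VHH when channel 10 exceeds 0.5, and the rotation
#' is recomposed from direction and angle.
#'
#' @param grid A [pose_grid()] (target or prediction).
#' @param cell_index 0-based integer length-3 cell index.
#' @return An [ab_pose()] with cell fields attached.
#' @export
decode_cell <- function(grid, cell_index) {
  stopifnot(inherits(grid, "pose_grid"))
  geometry <- grid$geometry
  ci <- as.integer(cell_index)
  stopifnot(all(ci >= 0), all(ci < geometry$dim))
  i <- ci + 1L
  v <- grid$channels[i[1], i[2], i[3], ]
  t_loc <- pmin(pmax(v[2:4], 0), geometry$cell_size - 1e-9)
  translation <- geometry$origin + ci * geometry$cell_size + t_loc
  dn <- sqrt(sum(v[5:7]^2))
  if (dn < 1e-12) stop("degenerate pose: zero-norm direction vector")
  direction <- v[5:7] / dn
  theta <- atan2(v[9], v[8])
  if (theta >= pi) theta <- -pi
  rotation <- recompose_rotation(direction, theta)
  pose <- ab_pose(rotation, translation,
                  ab_class = if (v[10] > 0.5) "vhh" else "fab",
                  geometry = geometry)
  pose
}

# All occupied cells (0-based index matrix) of a ground-truth grid.
occupied_cells <- function(grid, threshold = 0.5) {
  w <- which(grid$channels[, , , 1] > threshold, arr.ind = TRUE)
  if (length(w) == 0) return(matrix(integer(0), ncol = 3))
  unname(w - 1L)
}

# Decode every occupied cell of a target grid back into poses.
decode_target <- function(grid) {
  cells <- occupied_cells(grid)
  lapply(seq_len(nrow(cells)), function(r) decode_cell(grid, cells[r, ]))
}
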