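#' 3D density grid
#'
#' Container for a cryo-EM density map: a 3D scalar field on a regular
#' lattice. Grid node `(i, j, k)` (0-based) sits at physical position
#' `origin + c(i, j, k) * voxel` in Angstrom. This node-centered convention is
#' used consistently for cropping, resampling and the pose codec.
#'
#' @param values 3D numeric array of density values.
#' @param voxel Voxel size in Angstrom; scalar or length-3 vector, all > 0.
#' @param origin Physical position (Angstrom) of node `(0, 0, 0)`; length 3.
#' @return An object of class `density_grid` with fields `values`, `voxel`,
#'   `origin`.
#' @export
density_grid <- function(values, voxel = 2, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  voxel <- rep_len(as.numeric(voxel), 3L)
  if (any(!is.finite(voxel)) || any(voxel <= 0))
    stop("`voxel` components must be strictly positive")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(values = values, voxel = voxel, origin = origin),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_grid> %d x %d x %d voxels, voxel %s A, origin (%s) A\n",
              d[1], d[2], d[3],
              paste(format(x$voxel, digits = 4), collapse = "/"),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  cat(sprintf("  values in [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.density_grid <- function(x) dim(x$values)

# Physical extent [lo, hi] per axis (positions of the first and last node).
grid_extent <- function(grid) {
  d <- dim(grid$values)
  list(lo = grid$origin, hi = grid$origin + (d - 1) * grid$voxel)
}

#' Normalize a density grid
#'
#' Standard map normalization: negative values are zeroed, then the grid is
#' divided by its maximum so values lie in `[0, 1]` with the maximum equal to 1.
#' An all-non-positive grid is returned as all zeros (no division). The
#' operation is idempotent.
#'
#' @param grid A [density_grid()].
#' @return A normalized `density_grid`.
#' @export
normalize_grid <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  v <- grid$values
  v[v < 0] <- 0
  m <- max(v)
  if (m > 0) v <- v / m
  density_grid(v, grid$voxel, grid$origin)
}

#' Crop a grid around a set of points
#'
#' Restricts the grid to the axis-aligned bounding box of `coords` expanded by
#' `margin` Angstrom on each side, intersected with the grid extent. Crop
#' bounds round outward to whole grid nodes, so the requested physical margin
#' is never shrunk.
#'
#' @param grid A [density_grid()].
#' @param coords Numeric matrix (n x 3) of Angstrom positions (a vector of
#'   length 3 is accepted for a single point).
#' @param margin Margin in Angstrom (>= 0) added on every side; default 25.
#' @return The cropped `density_grid` with its origin updated.
#' @export
crop_to_structure <- function(grid, coords, margin = 25) {
  stopifnot(inherits(grid, "density_grid"))
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3, byrow = TRUE)
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("`coords` must be non-empty")
  if (margin < 0) stop("`margin` must be >= 0")
  d <- dim(grid$values)
  lo <- apply(coords, 2, min) - margin
  hi <- apply(coords, 2, max) + margin
  # outward rounding to whole nodes, then clamp to the available extent
  i_lo <- pmax(0L, as.integer(floor((lo - grid$origin) / grid$voxel + 1e-9)))
  i_hi <- pmin(d - 1L, as.integer(ceiling((hi - grid$origin) / grid$voxel - 1e-9)))
  if (any(i_hi < i_lo))
    stop("crop region lies entirely outside the map")
  v <- grid$values[(i_lo[1] + 1):(i_hi[1] + 1),
                   (i_lo[2] + 1):(i_hi[2] + 1),
                   (i_lo[3] + 1):(i_hi[3] + 1), drop = FALSE]
  density_grid(v, grid$voxel, grid$origin + i_lo * grid$voxel)
}

#' Resample a grid to a new voxel size
#'
#' Trilinear interpolation onto a new lattice with the same origin, using the
#' largest lattice that stays inside the source extent (so the extent can
#' shrink by up to one target voxel per axis, and interpolation never has to
#' invent values outside the data; positions outside the source extent would
#' interpolate to 0). Constants are preserved exactly, resampling to the
#' source voxel size is the identity, and resampling a constant field to
#' another voxel size and back reproduces it exactly.
#'
#' @param grid A [density_grid()].
#' @param target_voxel Target voxel size in Angstrom (> 0); scalar or length 3.
#' @return The resampled `density_grid`.
#' @export
resample_grid <- function(grid, target_voxel = 2) {
  stopifnot(inherits(grid, "density_grid"))
  tv <- rep_len(as.numeric(target_voxel), 3L)
  if (any(tv <= 0)) stop("`target_voxel` must be > 0")
  d <- dim(grid$values)
  if (isTRUE(all.equal(tv, grid$voxel, tolerance = 1e-12))) return(grid)
  span <- (d - 1) * grid$voxel
  nd <- as.integer(floor(span / tv + 1e-9)) + 1L
  nd <- pmax(nd, 1L)
  # fractional source indices of the new nodes, per axis
  ax <- lapply(1:3, function(k) (seq_len(nd[k]) - 1) * tv[k] / grid$voxel[k])
  fi <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  vals <- trilinear_at(grid$values, fi$x, fi$y, fi$z)
  density_grid(array(vals, nd), tv, grid$origin)
}

# Trilinear interpolation of `arr` at fractional 0-based indices; zero outside.
trilinear_at <- function(arr, fx, fy, fz) {
  d <- dim(arr)
  out <- numeric(length(fx))
  inside <- fx > -1 & fx < d[1] & fy > -1 & fy < d[2] & fz > -1 & fz < d[3]
  if (!any(inside)) return(out)
  fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
  x0 <- floor(fx); y0 <- floor(fy); z0 <- floor(fz)
  wx <- fx - x0; wy <- fy - y0; wz <- fz - z0
  acc <- numeric(length(fx))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- x0 + dx; iy <- y0 + dy; iz <- z0 + dz
    w <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
         (if (dz) wz else 1 - wz)
    ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3] & w > 0
    if (any(ok)) {
      lin <- ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok]) + 1
      acc[ok] <- acc[ok] + w[ok] * arr[lin]
    }
  }
  out[inside] <- acc
  out
}
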