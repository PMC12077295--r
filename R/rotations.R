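#' @title Rotation utilities and the direction/angle pose parameterization
#'
#' @description
#' Antibody orientations are represented by a proper rotation `R` applied to a
#' fixed template whose canonical binding axis is the unit vector `u_z`
#' (center of mass toward the CDR tips). `R` is decomposed into the predicted
#' binding direction `p = R u_z` and a residual in-plane angle `theta` about
#' `p`, with the fixed convention
#'
#'   `R = R_axis(p, theta) %*% R_min(u_z -> p)`
#'
#' where `R_min` is the minimal rotation taking `u_z` onto `p` (rotation about
#' `u_z x p`). The direction is easier to learn than the full rotation because
#' canonical antigen binding happens through the CDRs; the residual angle is
#' regressed as `(cos theta, sin theta)` to avoid the branch cut.
#'
#' @name rotations
NULL

# Rodrigues rotation about unit `axis` by `angle` (radians).
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Minimal rotation taking unit vector `u` onto unit vector `p` (about u x p).
# Antipodal degeneracy (p ~ -u): fixed 180-degree rotation about the template
# x-axis, a deterministic tie-break.
minimal_rotation <- function(u, p) {
  c_ <- sum(u * p)
  if (c_ < -1 + 1e-6) {
    # p is (numerically) -u: rotate 180 degrees about an axis orthogonal to u
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ref - sum(ref * u) * u
    return(rotation_about_axis(ax, pi))
  }
  v <- c(u[2] * p[3] - u[3] * p[2],
         u[3] * p[1] - u[1] * p[3],
         u[1] * p[2] - u[2] * p[1])
  s <- sqrt(sum(v^2))
  if (s < 1e-12) return(diag(3))
  rotation_about_axis(v / s, atan2(s, c_))
}

#' Decompose a rotation into binding direction and residual angle
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param u_z Template canonical axis (unit 3-vector), default `c(0, 0, 1)`.
#' @return List with `direction` (unit 3-vector `rotation %*% u_z`) and
#'   `angle` (radians in `[-pi, pi)`) such that
#'   [recompose_rotation()] reproduces `rotation`.
#' @export
decompose_rotation <- function(rotation, u_z = c(0, 0, 1)) {
  check_rotation(rotation)
  p <- as.numeric(rotation %*% u_z)
  p <- p / sqrt(sum(p^2))
  R_min <- minimal_rotation(u_z, p)
  # residual rotation about p: R_axis = rotation %*% t(R_min)
  Q <- rotation %*% t(R_min)
  # for a rotation about known axis p: tr(Q) = 1 + 2 cos(theta),
  # skew(Q) = sin(theta) [p]_x
  vec <- c(Q[3, 2] - Q[2, 3], Q[1, 3] - Q[3, 1], Q[2, 1] - Q[1, 2]) / 2
  s <- sum(vec * p)
  c_ <- (sum(diag(Q)) - 1) / 2
  theta <- atan2(s, c_)
  if (theta >= pi) theta <- -pi
  list(direction = p, angle = theta)
}

#' Recompose a rotation from binding direction and residual angle
#'
#' @param direction Unit 3-vector `p`.
#' @param angle Residual angle about `direction`, radians.
#' @param u_z Template canonical axis, default `c(0, 0, 1)`.
#' @return 3x3 proper rotation `R_axis(direction, angle) %*% R_min(u_z -> direction)`.
#' @export
recompose_rotation <- function(direction, angle, u_z = c(0, 0, 1)) {
  n <- sqrt(sum(direction^2))
  if (n < 1e-12) stop("zero-norm direction vector")
  p <- direction / n
  rotation_about_axis(p, angle) %*% minimal_rotation(u_z, p)
}

check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)))
    stop("rotation must be a 3x3 matrix")
  if (max(abs(t(R) %*% R - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("matrix is not a proper rotation (orthogonal, det +1)")
  invisible(TRUE)
}

# Haar-uniform random rotations via normalized quaternions.
random_rotation <- function(n = 1) {
  qs <- matrix(stats::rnorm(4 * n), n, 4)
  qs <- qs / sqrt(rowSums(qs^2))
  out <- lapply(seq_len(n), function(i) quat_to_matrix(qs[i, ]))
  if (n == 1) out[[1]] else out
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

# The 8-element augmentation subgroup: the four 90-degree rotations about z,
# each optionally composed with the 180-degree rotation about x.
grid_rotation_group <- function() {
  Rz <- function(k) rotation_about_axis(c(0, 0, 1), k * pi / 2)
  Rx <- rotation_about_axis(c(1, 0, 0), pi)
  out <- list()
  for (k in 0:3) out[[k + 1]] <- round(Rz(k))
  for (k in 0:3) out[[k + 5]] <- round(Rx %*% Rz(k))
  out
}
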