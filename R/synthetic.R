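#' Synthetic map specification
#'
#' Conditions for the synthetic density maps used to exercise the pipeline
#' end-to-end without any downloads. A map contains `n_antibodies` rigidly
#' placed pseudo-template densities (Fab or VHH) at Haar-uniform random
#' rotations and uniform positions at least `min_separation` apart, plus
#' antigen-like decoy blobs and additive Gaussian noise. The density model is
#' a sum of atom-centered isotropic Gaussians whose width emulates the map
#' resolution through the FWHM convention `sigma = resolution / 2.355`;
#' maps are sampled on a 2 Angstrom lattice and normalized like real maps
#' (negatives zeroed, divided by the maximum).
#'
#' When `n_antibodies` is NULL, each map draws its count from a Poisson with
#' mean 2.25 (the mean number of Fabs per system in curated antibody cryo-EM
#' corpora) truncated to 0..6.
#'
#' @param extent Map edge length in Angstrom (scalar or length 3).
#' @param voxel Voxel size in Angstrom (default 2).
#' @param n_antibodies Antibody count per map: a fixed integer, a vector to
#'   sample from uniformly, or NULL for the truncated-Poisson default.
#' @param vhh_fraction Probability that an antibody is a VHH rather than a
#'   Fab (default 0.3, roughly the VHH share of curated corpora).
#' @param sigma Gaussian smearing width in Angstrom (default 3.4,
#'   i.e. ~8 Angstrom resolution).
#' @param n_decoys Decoy blob count: fixed integer or vector to sample from.
#' @param noise_sd Additive Gaussian noise, as a fraction of the peak signal.
#' @param min_separation Minimum distance between antibody centers (Angstrom).
#'   The default 30 is the contact distance of two ~25 Angstrom globular
#'   variable domains (rigid molecules cannot interpenetrate) and comfortably
#'   guarantees that no two antibodies share an 8 Angstrom cell (which only
#'   needs 20).
#' @param boundary_pad Minimum distance of antibody centers from the map
#'   boundary (Angstrom).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(extent = 160, voxel = 2, n_antibodies = NULL,
                           vhh_fraction = 0.3, sigma = 3.4, n_decoys = 0:2,
                           noise_sd = 0.05, min_separation = 30,
                           boundary_pad = 20) {
  stopifnot(all(extent > 0), voxel > 0, sigma > 0, noise_sd >= 0,
            min_separation >= 0, vhh_fraction >= 0, vhh_fraction <= 1)
  structure(list(extent = rep_len(as.numeric(extent), 3L), voxel = voxel,
                 n_antibodies = n_antibodies, vhh_fraction = vhh_fraction,
                 sigma = sigma, n_decoys = n_decoys, noise_sd = noise_sd,
                 min_separation = min_separation, boundary_pad = boundary_pad),
            class = "synthetic_spec")
}

# Accumulate sum of unit-height Gaussians centered at `coords` into `acc`,
# evaluating each atom only within a 4-sigma box (the tail beyond is < 4e-4).
accumulate_gaussians <- function(acc, coords, origin, voxel, sigma) {
  d <- dim(acc)
  rad <- ceiling(4 * sigma / voxel)
  inv2s2 <- 1 / (2 * sigma^2)
  for (r in seq_len(nrow(coords))) {
    ci <- (coords[r, ] - origin) / voxel
    lo <- pmax(floor(ci) - rad, 0)
    hi <- pmin(ceiling(ci) + rad, d - 1)
    if (any(hi < lo)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    gx <- exp(-((xs - ci[1]) * voxel)^2 * inv2s2)
    gy <- exp(-((ys - ci[2]) * voxel)^2 * inv2s2)
    gz <- exp(-((zs - ci[3]) * voxel)^2 * inv2s2)
    blk <- outer(outer(gx, gy), gz)
    acc[xs + 1, ys + 1, zs + 1] <- acc[xs + 1, ys + 1, zs + 1] + blk
  }
  acc
}

#' Simulate a density map with known antibody poses
#'
#' Draws poses, renders the Gaussian-smeared density of placed pseudo
#' templates and decoys, adds noise, and normalizes. The returned poses are
#' the exact ground truth (the translation is the placed template's center of
#' mass).
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; the same seed reproduces the map bit-for-bit.
#' @param origin Physical origin of the map (default `c(0, 0, 0)`).
#' @return List with `grid` (normalized [density_grid()]) and `poses`
#'   (list of [ab_pose()]).
#' @export
simulate_map <- function(spec, seed = 0, origin = c(0, 0, 0)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  d <- as.integer(floor(spec$extent / spec$voxel)) + 1L
  acc <- array(0, d)

  n_ab <- spec$n_antibodies
  if (is.null(n_ab)) {
    n_ab <- min(stats::rpois(1, 2.25), 6L)
  } else if (length(n_ab) > 1) {
    n_ab <- sample(n_ab, 1)
  }
  n_ab <- as.integer(n_ab)

  lo <- origin + spec$boundary_pad
  hi <- origin + spec$extent - spec$boundary_pad
  if (n_ab > 0 && any(hi <= lo))
    stop("map extent too small for the requested boundary pad")
  centers <- matrix(0, 0, 3)
  for (i in seq_len(n_ab)) {
    placed <- FALSE
    for (try in 1:200) {
      p <- stats::runif(3, lo, hi)
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, p)^2))) >= spec$min_separation) {
        centers <- rbind(centers, p)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(
        "could not place %d antibodies %g Angstrom apart in this extent",
        n_ab, spec$min_separation))
  }

  poses <- vector("list", n_ab)
  templates <- list(fab = make_pseudo_template("fab"),
                    vhh = make_pseudo_template("vhh"))
  for (i in seq_len(n_ab)) {
    cls <- if (stats::runif(1) < spec$vhh_fraction) "vhh" else "fab"
    R <- random_rotation()
    t_ <- centers[i, ]
    poses[[i]] <- ab_pose(R, t_, ab_class = cls)
    at <- templates[[cls]]$coords %*% t(R)
    at <- sweep(at, 2, -t_)
    acc <- accumulate_gaussians(acc, at, origin, spec$voxel, spec$sigma)
  }

  n_dec <- if (length(spec$n_decoys) > 1) sample(spec$n_decoys, 1) else
    as.integer(spec$n_decoys)
  for (k in seq_len(n_dec)) {
    # antigen-like blob: a rescaled lobe at a random pose, kept away from
    # antibody centers so blobs do not swallow the ground truth; scales are
    # kept away from 1 so a decoy is never congruent to the VHH template
    # (labels must stay identifiable)
    sc <- if (stats::runif(1) < 0.5) stats::runif(1, 0.55, 0.8) else
      stats::runif(1, 1.25, 1.5)
    base <- make_pseudo_template("vhh")$coords * sc
    for (try in 1:100) {
      p <- stats::runif(3, origin + 10, origin + spec$extent - 10)
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, p)^2))) >= 25) break
    }
    at <- base %*% t(random_rotation())
    at <- sweep(at, 2, -p)
    acc <- accumulate_gaussians(acc, at, origin, spec$voxel, spec$sigma)
  }

  if (spec$noise_sd > 0 && max(acc) > 0)
    acc <- acc + stats::rnorm(length(acc), 0, spec$noise_sd * max(acc))
  grid <- normalize_grid(density_grid(acc, spec$voxel, origin))
  list(grid = grid, poses = poses)
}

#' Generate a dataset of simulated maps with encoded targets
#'
#' @param n_maps Number of maps.
#' @param spec A [synthetic_spec()].
#' @param seed Base seed; map `i` uses `seed + i`, so datasets are
#'   reproducible and maps mutually independent.
#' @param cell_size Pose-grid cell size in Angstrom (default 8).
#' @return List of examples, each with `grid`, `target` (ground-truth
#'   [pose_grid()]) and `poses`.
#' @export
make_dataset <- function(n_maps, spec = synthetic_spec(), seed = 0,
                         cell_size = 8) {
  stopifnot(n_maps >= 1)
  stride <- as.integer(round(cell_size / spec$voxel))
  lapply(seq_len(n_maps), function(i) {
    sim <- simulate_map(spec, seed = seed + i)
    geom <- geometry_for_grid(sim$grid, stride)
    list(grid = sim$grid, target = encode_poses(sim$poses, geom),
         poses = sim$poses)
  })
}
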