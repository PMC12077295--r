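#' Antibody template structure
#'
#' A fixed template whose rigid placements represent antibodies. The template
#' is stored centered (center of mass at the zero point) with its canonical
#' binding axis `u_z` pointing from the center of mass toward the CDR tips.
#' Detection then reduces to predicting, per antibody, the rotation and
#' translation that place this template in the map.
#'
#' @param coords N x 3 matrix of atom coordinates (Angstrom); they are
#'   re-centered so the center of mass is exactly zero.
#' @param ab_class `"fab"` or `"vhh"`.
#' @param u_z Canonical axis; normalized to unit length.
#' @param atom_names,resno,chain Optional per-atom metadata used for PDB
#'   emission (defaults: CA atoms, sequential residue numbers, chain A).
#' @param sequence Optional one-letter residue sequence (one per atom row)
#'   used for sequence-based superposition onto real structures.
#' @return An object of class `ab_template`.
#' @export
ab_template <- function(coords, ab_class = c("fab", "vhh"), u_z = c(0, 0, 1),
                        atom_names = NULL, resno = NULL, chain = NULL,
                        sequence = NULL) {
  ab_class <- match.arg(ab_class)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  coords <- sweep(coords, 2, colMeans(coords))
  nrm <- sqrt(sum(u_z^2))
  if (nrm < 1e-12) stop("u_z must be non-zero")
  n <- nrow(coords)
  structure(list(
    coords = coords,
    u_z = u_z / nrm,
    ab_class = ab_class,
    atom_names = atom_names %||% rep("CA", n),
    resno = resno %||% seq_len(n),
    chain = chain %||% rep("A", n),
    sequence = sequence
  ), class = "ab_template")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ab_template <- function(x, ...) {
  cat(sprintf("<ab_template> class %s, %d pseudo-atoms, u_z (%s)\n",
              x$ab_class, nrow(x$coords),
              paste(format(x$u_z, digits = 3), collapse = ", ")))
  invisible(x)
}

#' Deterministic pseudo-atomic antibody template
#'
#' Builds a synthetic stand-in for a real antibody template: an Fv-like shape
#' made of two ~25 Angstrom globular lobes (the heavy- and light-chain
#' variable domains) stacked along `u_z = (0, 0, 1)` for the Fab class, and a
#' single lobe for the VHH class. Atom positions come from a deterministic
#' Fibonacci-sphere filling, so every call returns the identical structure.
#' The second Fab lobe is laterally offset so the shape has no rotational
#' symmetry about `u_z` and the in-plane angle is identifiable from density.
#'
#' @param ab_class `"fab"` or `"vhh"`.
#' @return An [ab_template()] (center of mass at zero, `u_z = c(0, 0, 1)`).
#' @export
make_pseudo_template <- function(ab_class = c("fab", "vhh")) {
  ab_class <- match.arg(ab_class)
  # deterministic filled ball: golden-angle spiral over 4 radial shells
  lobe <- function(center, radius, n) {
    sh <- round(n * c(0.08, 0.17, 0.30, 0.45))
    sh[1] <- n - sum(sh[-1])
    pts <- NULL
    for (s in seq_along(sh)) {
      m <- sh[s]
      r <- radius * (s / length(sh))^(1 / 1.5)
      i <- seq_len(m) - 0.5
      phi <- acos(1 - 2 * i / m)
      theta <- pi * (1 + sqrt(5)) * i
      pts <- rbind(pts, cbind(r * sin(phi) * cos(theta),
                              r * sin(phi) * sin(theta),
                              r * cos(phi)))
    }
    sweep(pts, 2, center, `+`)
  }
  if (ab_class == "fab") {
    lower <- lobe(c(0, 0, -12.5), 12.5, 100)   # one variable domain
    upper <- lobe(c(3, 0, 12.5), 11, 100)      # the other, laterally offset
    coords <- rbind(lower, upper)
    chain <- rep(c("H", "L"), c(nrow(lower), nrow(upper)))
  } else {
    coords <- lobe(c(0, 0, 0), 12.5, 100)
    chain <- rep("N", nrow(coords))
  }
  ab_template(coords, ab_class, u_z = c(0, 0, 1), chain = chain)
}

#' Read a template from a PDB file
#'
#' Extracts C-alpha atoms (coordinates, residue numbers, chains and one-letter
#' sequence) from a PDB file and centers them, producing an [ab_template()]
#' usable both for superposition onto other antibodies and for PDB emission.
#' `u_z` must be supplied by the caller in the file's frame (it is rotated
#' into the centered frame unchanged, since centering is a pure translation).
#'
#' @param path PDB file path.
#' @param ab_class `"fab"` or `"vhh"`.
#' @param u_z Canonical binding axis in the file's coordinate frame.
#' @param chains Optional chain ids to keep (e.g. `c("H", "L")` for an Fv).
#' @return An [ab_template()].
#' @export
read_template_pdb <- function(path, ab_class = c("fab", "vhh"),
                              u_z = c(0, 0, 1), chains = NULL) {
  ab_class <- match.arg(ab_class)
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB templates requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, "calpha", chain = chains, verbose = FALSE)
  at <- pdb$atom[sel$atom, ]
  if (nrow(at) < 1) stop("no C-alpha atoms found in ", path)
  seq1 <- unname(bio3d::aa321(at$resid))
  ab_template(as.matrix(at[, c("x", "y", "z")]), ab_class, u_z = u_z,
              atom_names = at$elety, resno = at$resno, chain = at$chain,
              sequence = seq1)
}
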