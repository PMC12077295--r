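#' Least-squares rigid superposition (Kabsch)
#'
#' Returns the proper rotation `R` and translation `t` minimizing
#' `sum_i || R p_i + t - q_i ||^2` for paired point sets, via SVD of the
#' cross-covariance with the determinant sign correction.
#'
#' @param p,q N x 3 matrices of paired coordinates (template and target).
#' @return List with `rotation` (3x3), `translation` (length 3) and `rmsd`
#'   (Angstrom) of the superposed pairs.
#' @export
kabsch <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(nrow(p) == nrow(q), ncol(p) == 3, ncol(q) == 3, nrow(p) >= 3)
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  H <- t(pc) %*% qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_ <- cq - as.numeric(R %*% cp)
  res <- sweep(p %*% t(R), 2, -t_) - q
  list(rotation = R, translation = t_,
       rmsd = sqrt(mean(rowSums(res^2))))
}

#' Superpose an antibody template onto an antibody structure
#'
#' Pairs template and target residues, then performs a least-squares rigid
#' (Kabsch) superposition of the paired C-alpha atoms with iterative outlier
#' rejection: pairs whose residual distance exceeds 2 standard deviations of
#' the residuals are dropped and the fit repeated, for up to 5 cycles. This
#' mirrors how structure-alignment tools refine a superposition to the
#' conserved core, which matters because CDR loops vary between antibodies.
#'
#' Pairing: if both sides carry sequences, residues are paired per chain by
#' global-local sequence alignment (BLOSUM62); otherwise the coordinate rows
#' are assumed already matched 1:1.
#'
#' @param template An [ab_template()].
#' @param target Either an N x 3 coordinate matrix matched 1:1 to the template
#'   atoms, or a list with `coords` (N x 3 C-alpha matrix), `sequence`
#'   (one-letter, one per row) and optionally `chain` (per-row chain ids).
#' @param min_matched Minimum number of matched residues required (default 50).
#' @param max_cycles Outlier-rejection cycles (default 5).
#' @return List with `rotation`, `translation` (mapping template coordinates
#'   onto the target), `rmsd` (final, after rejection) and `n_matched`.
#' @export
superpose_template <- function(template, target, min_matched = 50,
                               max_cycles = 5) {
  stopifnot(inherits(template, "ab_template"))
  if (is.matrix(target) || (is.numeric(target) && !is.list(target))) {
    tc <- as.matrix(target)
    pairs <- cbind(seq_len(nrow(tc)), seq_len(nrow(tc)))
    target_coords <- tc
  } else {
    if (is.null(template$sequence) || is.null(target$sequence))
      stop("sequence-based pairing requires sequences on both template and target")
    pairs <- pair_residues(template, target)
    target_coords <- as.matrix(target$coords)
  }
  if (nrow(pairs) < min_matched)
    stop(sprintf("alignment failure: only %d residues matched (need >= %d)",
                 nrow(pairs), min_matched))
  keep <- seq_len(nrow(pairs))
  fit <- NULL
  for (cycle in seq_len(max_cycles)) {
    fit <- kabsch(template$coords[pairs[keep, 1], , drop = FALSE],
                  target_coords[pairs[keep, 2], , drop = FALSE])
    moved <- sweep(template$coords[pairs[keep, 1], , drop = FALSE] %*%
                     t(fit$rotation), 2, -fit$translation)
    d <- sqrt(rowSums((moved - target_coords[pairs[keep, 2], , drop = FALSE])^2))
    cut <- mean(d) + 2 * stats::sd(d)
    inl <- d <= cut | !is.finite(cut)
    if (all(inl) || sum(inl) < max(3, min_matched / 2)) break
    keep <- keep[inl]
  }
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = fit$rmsd, n_matched = length(keep))
}

# Pair template and target C-alpha rows by per-chain sequence alignment.
pair_residues <- function(template, target) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("sequence pairing requires the Biostrings package")
  t_chain <- template$chain %||% rep("A", nrow(template$coords))
  g_chain <- target$chain %||% rep("A", nrow(target$coords))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  pairs <- NULL
  used_g <- character(0)
  for (tc in unique(t_chain)) {
    ti <- which(t_chain == tc)
    tseq <- paste(template$sequence[ti], collapse = "")
    best <- NULL
    for (gc in setdiff(unique(g_chain), used_g)) {
      gi <- which(g_chain == gc)
      gseq <- paste(target$sequence[gi], collapse = "")
      al <- Biostrings::pairwiseAlignment(tseq, gseq, substitutionMatrix = mat,
                                          gapOpening = 10, gapExtension = 0.5,
                                          type = "local")
      if (is.null(best) || Biostrings::score(al) > best$score)
        best <- list(score = Biostrings::score(al), al = al, gi = gi, ti = ti,
                     gc = gc)
    }
    if (is.null(best)) next
    used_g <- c(used_g, best$gc)
    pa <- aligned_index_pairs(best$al)
    if (nrow(pa) > 0)
      pairs <- rbind(pairs, cbind(best$ti[pa[, 1]], best$gi[pa[, 2]]))
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2)
  pairs
}

# Matched (pattern, subject) position pairs of a pairwiseAlignment, gaps removed.
aligned_index_pairs <- function(al) {
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  pi_ <- Biostrings::start(Biostrings::pattern(al)) - 1L
  si <- Biostrings::start(Biostrings::subject(al)) - 1L
  out <- matrix(integer(0), ncol = 2)
  for (k in seq_along(pat)) {
    pgap <- pat[k] == "-"
    sgap <- sub[k] == "-"
    if (!pgap) pi_ <- pi_ + 1L
    if (!sgap) si <- si + 1L
    if (!pgap && !sgap) out <- rbind(out, c(pi_, si))
  }
  out
}
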