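#' Superlevel-set persistence of an occupancy grid
#'
#' Zero-dimensional persistence of the superlevel sets of a 3D scalar field:
#' a threshold sweeps down from the grid maximum, cells activate as the
#' threshold passes their value, and connected components (6-connectivity,
#' face adjacency, by default) are tracked. A component is born at a local
#' maximum (its seed) and dies when it merges into a component with a higher
#' birth (the elder rule); the globally surviving component's death is the
#' grid minimum, so a single-peak grid yields one finite lifetime. Lifetimes
#' `birth - death` rank detection prominence: adjacent high cells belonging to
#' one antibody form a single long-lived component, which is what makes this
#' a non-maximal suppression.
#'
#' Ties (equal values, equal lifetimes) are broken by lexicographic cell
#' index, so the output is deterministic.
#'
#' @param occupancy 3D numeric array of finite values.
#' @param connectivity 6 (face adjacency, default) or 26.
#' @return A data.frame with one row per component, columns `seed_x`,
#'   `seed_y`, `seed_z` (0-based cell index of the component maximum),
#'   `birth`, `death`, `lifetime`, sorted by decreasing lifetime.
#' @export
persistence_components <- function(occupancy, connectivity = 6) {
  stopifnot(length(dim(occupancy)) == 3, all(is.finite(occupancy)))
  d <- dim(occupancy)
  n <- prod(d)
  v <- as.numeric(occupancy)

  offs <- neighbor_offsets(connectivity)
  # process cells by decreasing value; ties by lexicographic (x,y,z) index,
  # which for 0-based (x + nx*y + nx*ny*z) is ascending linear order
  ord <- order(-v, seq_len(n))
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)  # activation order

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  seed <- integer(n)       # per-root: seed cell of its component
  birth <- numeric(n)
  active <- logical(n)
  deaths <- numeric(n); dseed <- integer(n); dbirth <- numeric(n)
  ndead <- 0L

  ix <- ((ord - 1L) %% d[1])
  iy <- ((ord - 1L) %/% d[1]) %% d[2]
  iz <- (ord - 1L) %/% (d[1] * d[2])

  for (t in seq_len(n)) {
    cell <- ord[t]
    cx <- ix[t]; cy <- iy[t]; cz <- iz[t]
    active[cell] <- TRUE
    seed[cell] <- cell
    birth[cell] <- v[cell]
    for (k in seq_len(nrow(offs))) {
      nx <- cx + offs[k, 1]; ny <- cy + offs[k, 2]; nz <- cz + offs[k, 3]
      if (nx < 0 || ny < 0 || nz < 0 || nx >= d[1] || ny >= d[2] || nz >= d[3])
        next
      nb <- 1L + nx + d[1] * (ny + d[2] * nz)
      if (!active[nb]) next
      ra <- find(cell); rb <- find(nb)
      if (ra == rb) next
      # elder rule: the component with the higher birth survives;
      # equal births -> the earlier-activated (lexicographically smaller) seed
      keep_a <- (birth[ra] > birth[rb]) ||
        (birth[ra] == birth[rb] && rank_of[seed[ra]] < rank_of[seed[rb]])
      win <- if (keep_a) ra else rb
      lose <- if (keep_a) rb else ra
      ndead <- ndead + 1L
      deaths[ndead] <- v[cell]
      dseed[ndead] <- seed[lose]
      dbirth[ndead] <- birth[lose]
      parent[lose] <- win      # seed/birth of the winner are unchanged
    }
  }
  # the survivor dies at the grid minimum
  root <- find(ord[1])
  surv <- ndead + 1L
  dseed[surv] <- seed[root]
  dbirth[surv] <- birth[root]
  deaths[surv] <- min(v)

  keep <- seq_len(surv)
  s0 <- dseed[keep] - 1L
  out <- data.frame(
    seed_x = s0 %% d[1],
    seed_y = (s0 %/% d[1]) %% d[2],
    seed_z = s0 %/% (d[1] * d[2]),
    birth = dbirth[keep],
    death = deaths[keep])
  out$lifetime <- out$birth - out$death
  # zero-lifetime bars from non-maximal cells (born and merged at the same
  # level) are not components; the survivor row is always kept so a constant
  # grid still yields exactly one component
  is_comp <- out$lifetime > 0
  is_comp[surv] <- TRUE
  out <- out[is_comp, , drop = FALSE]
  ord2 <- order(-out$lifetime, s0[is_comp])
  out <- out[ord2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 6) {
    matrix(c(-1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1),
           ncol = 3, byrow = TRUE)
  } else if (connectivity == 26) {
    g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
}

#' Select detections from persistence components
#'
#' Two selection modes: `num` keeps the top `k` components by lifetime (fewer
#' if fewer exist), for when the number of antibodies is known; `thresh`
#' keeps every component with lifetime strictly above `tau` (default 0.2),
#' the fully automatic mode that also estimates how many antibodies the map
#' contains.
#'
#' @param components Output of [persistence_components()].
#' @param mode `"thresh"` or `"num"`.
#' @param k Number of detections to keep in `num` mode.
#' @param tau Lifetime threshold in `thresh` mode (default 0.2).
#' @return The selected rows, still sorted by decreasing lifetime.
#' @export
select_detections <- function(components, mode = c("thresh", "num"), k = NULL,
                              tau = 0.2) {
  mode <- match.arg(mode)
  if (mode == "num") {
    if (is.null(k) || k < 0) stop("`num` mode requires k >= 0")
    components[seq_len(min(k, nrow(components))), , drop = FALSE]
  } else {
    if (tau < 0) stop("`tau` must be >= 0")
    components[components$lifetime > tau, , drop = FALSE]
  }
}
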