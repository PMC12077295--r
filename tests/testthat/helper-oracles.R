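# Independent oracles used across the suite. They deliberately use different
# algorithms / data structures than the package implementations they check.

# --- persistence oracle: explicit threshold sweep -----------------------------
# For every distinct grid value (descending), label the connected components
# of the superlevel set with igraph, then track component identities through
# their seed cells: a new region is a birth; a region containing several
# alive seeds kills all but the highest-born (ties: smaller linear seed).
sweep_persistence_oracle <- function(v) {
  d <- dim(v)
  n <- prod(d)
  vals <- sort(unique(as.numeric(v)), decreasing = TRUE)
  lin <- seq_len(n)
  xs <- (lin - 1) %% d[1]
  ys <- ((lin - 1) %/% d[1]) %% d[2]
  zs <- (lin - 1) %/% (d[1] * d[2])
  edge_list <- function(mask) {
    e <- NULL
    for (o in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      ok <- xs + o[1] < d[1] & ys + o[2] < d[2] & zs + o[3] < d[3]
      a <- lin[ok]
      b <- a + o[1] + d[1] * o[2] + d[1] * d[2] * o[3]
      keep <- mask[a] & mask[b]
      if (any(keep)) e <- rbind(e, cbind(a[keep], b[keep]))
    }
    e
  }
  seeds <- integer(0); births <- numeric(0); deaths <- numeric(0)
  alive <- logical(0)
  for (t in vals) {
    mask <- as.numeric(v) >= t
    cells <- lin[mask]
    e <- edge_list(mask)
    g <- igraph::make_graph(edges = if (is.null(e)) integer(0)
                            else as.vector(t(e)),
                            n = n, directed = FALSE)
    comp <- igraph::components(g)$membership
    for (L in unique(comp[cells])) {
      members <- cells[comp[cells] == L]
      olds <- which(alive & seeds %in% members)
      if (length(olds) == 0) {
        cv <- as.numeric(v)[members]
        seed <- members[order(-cv, members)][1]
        seeds <- c(seeds, seed); births <- c(births, t)
        deaths <- c(deaths, NA_real_); alive <- c(alive, TRUE)
      } else if (length(olds) > 1) {
        eldest <- olds[order(-births[olds], seeds[olds])][1]
        for (o2 in setdiff(olds, eldest)) {
          deaths[o2] <- t; alive[o2] <- FALSE
        }
      }
    }
  }
  deaths[alive] <- min(v)
  data.frame(seed = seeds, birth = births, death = deaths,
             lifetime = births - deaths)
}

# count of regional maxima (cells strictly above all face neighbors); only
# valid for grids without ties among neighbors
count_regional_maxima <- function(v) {
  d <- dim(v)
  pad <- array(-Inf, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  ismax <- array(TRUE, d)
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    nb <- pad[2:(d[1] + 1) + o[1], 2:(d[2] + 1) + o[2], 2:(d[3] + 1) + o[3]]
    ismax <- ismax & (v > nb)
  }
  sum(ismax)
}

# --- assignment oracle: exhaustive permutation search -------------------------
# Minimum-total-cost assignment of rows to columns (all row-permutations of
# the smaller side), returning total cost and the chosen pairs.
brute_force_assignment <- function(D) {
  np <- nrow(D); ng <- ncol(D)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf; best_pairs <- NULL
  if (np <= ng) {
    for (p in perms(seq_len(ng))) {
      sel <- p[seq_len(np)]
      cost <- sum(D[cbind(seq_len(np), sel)])
      if (cost < best) { best <- cost; best_pairs <- cbind(seq_len(np), sel) }
    }
  } else {
    for (p in perms(seq_len(np))) {
      sel <- p[seq_len(ng)]
      cost <- sum(D[cbind(sel, seq_len(ng))])
      if (cost < best) { best <- cost; best_pairs <- cbind(sel, seq_len(ng)) }
    }
  }
  list(cost = best, pairs = best_pairs)
}

# --- misc helpers -------------------------------------------------------------
# shared state between consecutive acceptance blocks (trained model reuse)
.acceptance_cache <- new.env(parent = emptyenv())

rand_rot <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  cryoab:::quat_to_matrix(q)
}

tiny_cfg <- function() unet_config(depth = 3, base_channels = 2, stride = 4)

# small single-antibody map for model tests: 16^3 voxels -> 4^3 cells
tiny_example <- function(seed = 7, extent = 30) {
  spec <- synthetic_spec(extent = extent, n_antibodies = 1, sigma = 4,
                         noise_sd = 0.02, n_decoys = 0, boundary_pad = 14,
                         min_separation = 0)
  sim <- simulate_map(spec, seed = seed)
  geom <- cryoab:::geometry_for_grid(sim$grid, 4L)
  list(grid = sim$grid, target = encode_poses(sim$poses, geom),
       poses = sim$poses)
}
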