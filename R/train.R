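#' Rotation / crop data augmentation
#'
#' Applies one of the 8 axis-aligned proper rotations (the subgroup of the
#' grid-rotation group generated by 90-degree rotations about z and the
#' 180-degree rotation about x) to a map and its ground-truth grid, then
#' crops 0-3 whole cells from each side. The rotation acts about the grid
#' center: the density array is permuted/reversed accordingly and every
#' ground-truth pose is decoded, rigidly transformed (`R' = Q R`,
#' `t' = Q (t - c) + c'`) and re-encoded, so all vector channels and the
#' residual angle stay consistent by construction. Antibodies whose owner
#' cell is cropped away are dropped.
#'
#' @param grid A [density_grid()].
#' @param target The matching ground-truth [pose_grid()].
#' @param rot_index Rotation 1..8 (1 = identity); drawn uniformly if NULL.
#' @param crop_cells 3 x 2 integer matrix of cells to remove per (axis, side),
#'   each in 0..3; drawn uniformly if NULL.
#' @param min_voxels Smallest allowed grid side after cropping (crops are
#'   reduced if they would undercut it).
#' @return List with `grid`, `target` and `poses` (the surviving poses).
#' @export
augment_example <- function(grid, target, rot_index = NULL, crop_cells = NULL,
                            min_voxels = 16L) {
  stopifnot(inherits(grid, "density_grid"), inherits(target, "pose_grid"))
  geom <- target$geometry
  stride <- as.integer(round(geom$cell_size / grid$voxel[1]))
  if (is.null(rot_index)) rot_index <- sample.int(8L, 1)
  if (is.null(crop_cells))
    crop_cells <- matrix(sample(0:3, 6, replace = TRUE), 3, 2)
  poses <- decode_target(target)

  Q <- grid_rotation_group()[[rot_index]]
  rot <- rotate_grid_90(grid, Q)
  c_old <- grid$origin + (dim(grid$values) - 1) * grid$voxel / 2
  c_new <- rot$origin + (dim(rot$values) - 1) * rot$voxel / 2
  poses <- lapply(poses, function(p)
    ab_pose(Q %*% p$rotation,
            as.numeric(Q %*% (p$translation - c_old)) + c_new,
            ab_class = p$ab_class))
  grid <- rot

  # crop whole cells from each side (kept aligned to cell boundaries)
  d <- dim(grid$values)
  max_lo <- pmax((d - min_voxels) %/% stride, 0L)
  lo_c <- pmin(crop_cells[, 1], max_lo)
  hi_c <- pmin(crop_cells[, 2], pmax((d - min_voxels) %/% stride - lo_c, 0L))
  lo <- lo_c * stride
  hi <- hi_c * stride
  v <- grid$values[(lo[1] + 1):(d[1] - hi[1]),
                   (lo[2] + 1):(d[2] - hi[2]),
                   (lo[3] + 1):(d[3] - hi[3]), drop = FALSE]
  grid <- density_grid(v, grid$voxel, grid$origin + lo * grid$voxel)

  new_geom <- geometry_for_grid(grid, stride)
  ext_hi <- new_geom$origin + new_geom$dim * new_geom$cell_size
  keep <- vapply(poses, function(p)
    all(p$translation >= new_geom$origin) && all(p$translation < ext_hi),
    logical(1))
  poses <- poses[keep]
  list(grid = grid, target = encode_poses(poses, new_geom), poses = poses)
}

# Rotate a density grid by a signed-permutation rotation about its center.
rotate_grid_90 <- function(grid, Q) {
  perm <- apply(abs(Q) > 0.5, 1, which)
  sgn <- Q[cbind(1:3, perm)]
  A <- aperm(grid$values, perm)
  idx <- lapply(1:3, function(i)
    if (sgn[i] < 0) rev(seq_len(dim(A)[i])) else seq_len(dim(A)[i]))
  A <- A[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  density_grid(A, grid$voxel[perm], grid$origin)
}

# Adam update; state holds first/second moments per parameter array.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (k in keys) {
        if (is.null(g[[k]])) stop("missing gradient for parameter ", k)
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^state$t)
      vh <- v / (1 - beta2^state$t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(t = state$t, m = r$m, v = r$v))
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

#' Train the detection network
#'
#' Minimizes the composite detection loss (focal occupancy + Sinkhorn
#' divergence + per-cell pose terms, see [total_loss()]) with Adam, one map
#' per step, optionally applying rotation/crop augmentation. Training is
#' fully reproducible for a fixed seed. If a validation set is given, the
#' parameters with the best validation loss are retained; otherwise the
#' final parameters are returned.
#'
#' @param model A `unet_model` from [new_detector()].
#' @param dataset List of examples, each a list with `grid` (a normalized
#'   [density_grid()]) and `target` (the ground-truth [pose_grid()]), as
#'   produced by [make_dataset()].
#' @param epochs Number of passes over the dataset.
#' @param lr Adam learning rate: a scalar, or a vector of per-epoch rates
#'   (recycled/truncated to `epochs`) for stepwise decay schedules.
#' @param weights A [loss_weights()].
#' @param seed RNG seed controlling example order and augmentation.
#' @param augment Apply rotation/crop augmentation (default TRUE).
#' @param crop_max Largest number of whole cells the augmentation may crop
#'   per side (0..3). The default 1 suits desk-scale maps of ~10 cells per
#'   axis, where larger crops would regularly remove an antibody's owner cell
#'   while leaving most of its density — i.e. mislabel it; on corpus-scale
#'   maps the conventional 3 is appropriate.
#' @param val_dataset Optional validation examples for checkpoint selection.
#' @param sinkhorn_tol Sup-norm convergence tolerance of the Sinkhorn
#'   potentials during training. The default 0.1 (on an Angstrom^2 potential
#'   scale) yields gradients accurate to ~1e-3 relative — ample for
#'   stochastic optimization — at roughly half the cost of a tight solve;
#'   reported loss values use the tight tolerance.
#' @param verbose Print per-epoch mean loss.
#' @return The trained `unet_model`, with a `history` data.frame (per-epoch
#'   mean training loss and, if available, validation loss) attached.
#' @export
train_detector <- function(model, dataset, epochs = 12, lr = 3e-3,
                           weights = loss_weights(), seed = 0, augment = TRUE,
                           crop_max = 1, val_dataset = NULL,
                           sinkhorn_tol = 0.1,
                           verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), length(dataset) >= 1)
  set.seed(seed)
  cfg <- model$cfg
  params <- model$params
  lr <- rep_len(lr, epochs)
  state <- list(t = 0, m = zeros_like(params), v = zeros_like(params))
  hist_train <- numeric(epochs)
  hist_val <- rep(NA_real_, epochs)
  best <- list(loss = Inf, params = params)

  for (ep in seq_len(epochs)) {
    idx <- sample(length(dataset))
    losses <- numeric(length(idx))
    for (j in seq_along(idx)) {
      ex <- dataset[[idx[j]]]
      if (augment) {
        aug <- augment_example(ex$grid, ex$target,
                               crop_cells = matrix(sample(0:crop_max, 6,
                                                          replace = TRUE),
                                                   3, 2))
        ex <- list(grid = aug$grid, target = aug$target)
      }
      st <- train_step(params, cfg, ex$grid, ex$target, weights, sinkhorn_tol)
      if (!is.finite(st$loss))
        stop(sprintf("NaN/Inf loss at epoch %d step %d: %s", ep, j,
                     paste(names(st$breakdown),
                           signif(st$breakdown, 3), collapse = " ")))
      up <- adam_step(params, st$grads, state, lr[ep])
      params <- up$params
      state <- up$state
      losses[j] <- st$loss
    }
    hist_train[ep] <- mean(losses)
    if (!is.null(val_dataset)) {
      vl <- mean(vapply(val_dataset, function(ex) {
        pg <- predict_grid(structure(list(params = params, cfg = cfg),
                                     class = "unet_model"), ex$grid)
        total_loss_impl(pg, ex$target, weights, with_grad = FALSE,
                        sinkhorn_tol = sinkhorn_tol)$total
      }, 0))
      hist_val[ep] <- vl
      if (vl < best$loss) best <- list(loss = vl, params = params)
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.4f%s", ep, hist_train[ep],
                      if (is.na(hist_val[ep])) ""
                      else sprintf("  val %.4f", hist_val[ep])))
  }
  if (!is.null(val_dataset) && is.finite(best$loss)) params <- best$params
  out <- structure(list(params = params, cfg = cfg), class = "unet_model")
  out$history <- data.frame(epoch = seq_len(epochs), train = hist_train,
                            val = hist_val)
  out
}

# One forward/backward pass on a single example; returns loss, breakdown and
# parameter gradients.
train_step <- function(params, cfg, grid, target, weights, sinkhorn_tol) {
  d <- dim(grid$values)
  m <- 2^cfg$depth
  pd <- as.integer(ceiling(d / m) * m)
  x <- array(0, c(pd, 1L))
  x[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), 1] <- grid$values
  fw <- unet_forward(params, x, cfg, keep = TRUE)
  nc <- as.integer(ceiling(d / cfg$stride))
  raw <- fw$out[seq_len(nc[1]), seq_len(nc[2]), seq_len(nc[3]), ,
                drop = FALSE]
  prob <- raw
  prob[, , , 1] <- sigmoid(raw[, , , 1])
  prob[, , , 10] <- sigmoid(raw[, , , 10])
  geom <- grid_geometry(nc, cfg$stride * grid$voxel[1], grid$origin)
  pred <- pose_grid(prob, geom, kind = "prediction")
  if (!all(dim(target$channels)[1:3] == nc))
    stop("target grid does not match the prediction extent")
  li <- total_loss_impl(pred, target, weights, with_grad = TRUE,
                        sinkhorn_tol = sinkhorn_tol)
  dprob <- li$grad
  # chain through the sigmoids on channels 1 and 10
  dprob[, , , 1] <- dprob[, , , 1] * prob[, , , 1] * (1 - prob[, , , 1])
  dprob[, , , 10] <- dprob[, , , 10] * prob[, , , 10] * (1 - prob[, , , 10])
  dout <- array(0, dim(fw$out))
  dout[seq_len(nc[1]), seq_len(nc[2]), seq_len(nc[3]), ] <- dprob
  grads <- unet_backward(params, cfg, fw$cache, dout)
  list(loss = li$total, breakdown = li$breakdown, grads = grads)
}
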