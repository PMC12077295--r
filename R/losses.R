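#' Loss weights
#'
#' Hyper-parameters of the composite detection loss. Defaults follow the
#' values used to train the detector: focal exponent `gamma = 4`,
#' positive-class weight `lam = 30`, per-cell pose weight `lam_s = 0.2`, and
#' VHH class weight `lam_n = 1000/400 = 2.5` (the VHH:Fab ratio in the
#' training corpus). `ot_blur` is the entropic length scale of the Sinkhorn
#' term in Angstrom (default 8, one grid cell) and `ot_scaling` its annealing
#' factor.
#'
#' @param gamma Focal exponent, >= 0.
#' @param lam Focal positive-class weight, > 0.
#' @param lam_s Weight of the per-cell pose/class terms, > 0.
#' @param lam_n VHH class weight inside the class focal term, > 0.
#' @param ot_blur Sinkhorn entropic scale (Angstrom), > 0.
#' @param ot_scaling Sinkhorn annealing factor in (0, 1).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(gamma = 4, lam = 30, lam_s = 0.2, lam_n = 1000 / 400,
                         ot_blur = 8, ot_scaling = 0.5) {
  stopifnot(gamma >= 0, lam > 0, lam_s >= 0, lam_n > 0, ot_blur > 0,
            ot_scaling > 0, ot_scaling < 1)
  structure(list(gamma = gamma, lam = lam, lam_s = lam_s, lam_n = lam_n,
                 ot_blur = ot_blur, ot_scaling = ot_scaling),
            class = "loss_weights")
}

PROB_CLAMP <- 1e-7

#' Weighted binary focal loss
#'
#' `-[lam * y * (1 - p)^gamma * log(p) + (1 - y) * p^gamma * log(1 - p)]`,
#' elementwise. The `(1 - p)^gamma` factor down-weights confidently correct
#' cells so training focuses on wrong predictions; `lam` counteracts the
#' extreme class imbalance of the occupancy grid (a handful of occupied cells
#' among thousands). The loss is >= 0 and minimized at `p = y`. Probabilities
#' are clamped to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param pred Predicted probabilities (any shape).
#' @param target Targets in `{0, 1}` (same shape).
#' @param gamma Focal exponent.
#' @param lam Positive-class weight.
#' @return Elementwise loss values, same shape as `pred`.
#' @export
focal_loss <- function(pred, target, gamma = 4, lam = 30) {
  p <- pmin(pmax(pred, PROB_CLAMP), 1 - PROB_CLAMP)
  -(lam * target * (1 - p)^gamma * log(p) +
      (1 - target) * p^gamma * log(1 - p))
}

# d focal / d pred (at the clamped probability).
focal_loss_grad <- function(pred, target, gamma = 4, lam = 30) {
  p <- pmin(pmax(pred, PROB_CLAMP), 1 - PROB_CLAMP)
  gpos <- lam * (gamma * (1 - p)^(gamma - 1) * log(p) - (1 - p)^gamma / p)
  gneg <- -gamma * p^(gamma - 1) * log(1 - p) + p^gamma / (1 - p)
  target * gpos + (1 - target) * gneg
}

#' Occupancy focal loss over a grid (L1)
#'
#' Sum of the weighted binary focal loss over all cells of the occupancy
#' channel.
#'
#' @param pred_grid,target_grid [pose_grid()]s sharing one geometry.
#' @param weights A [loss_weights()].
#' @return Scalar loss.
#' @export
l1_occupancy <- function(pred_grid, target_grid, weights = loss_weights()) {
  check_same_geometry(pred_grid, target_grid)
  sum(focal_loss(pred_grid$channels[, , , 1], target_grid$channels[, , , 1],
                 weights$gamma, weights$lam))
}

#' Occupancy Sinkhorn divergence (L2)
#'
#' Both occupancy channels are viewed as measures on cell-center coordinates
#' (Angstrom), normalized to total mass 1 after adding `1e-8` to every cell
#' (guarding all-zero predictions), and compared with the debiased Sinkhorn
#' divergence with squared Euclidean cost at entropic scale `ot_blur`.
#'
#' @inheritParams l1_occupancy
#' @return Scalar loss (Angstrom^2 scale).
#' @export
l2_sinkhorn <- function(pred_grid, target_grid, weights = loss_weights()) {
  l2_sinkhorn_impl(pred_grid, target_grid, weights)$value
}

l2_sinkhorn_impl <- function(pred_grid, target_grid, weights, tol = 1e-9) {
  check_same_geometry(pred_grid, target_grid)
  geom <- target_grid$geometry
  if (sum(target_grid$channels[, , , 1]) <= 0)
    stop("l2_sinkhorn requires at least one occupied target cell")
  p <- pred_grid$channels[, , , 1] + 1e-8
  g <- target_grid$channels[, , , 1] + 1e-8
  sp <- sum(p)
  axis_coords <- lapply(1:3, function(k)
    geom$origin[k] + (seq_len(geom$dim[k]) - 0.5) * geom$cell_size)
  sd_ <- sinkhorn_divergence_grid(p, g, axis_coords, blur = weights$ot_blur,
                                  scaling = weights$ot_scaling, tol = tol)
  # chain rule through the mass normalization a = p / sum(p)
  ga <- sd_$grad_a
  abar <- p / sp
  grad_pred <- (ga - sum(abar * ga)) / sp
  list(value = sd_$value, grad_pred = grad_pred)
}

#' Per-cell pose losses (L3, L4, L5)
#'
#' Evaluated only at ground-truth occupied cells. `l3_offset` is the mean
#' squared error of the intra-cell offset (Angstrom). `l4_direction` is
#' `1 - <v, p> + (||v|| - 1)^2` for the predicted direction vector `v` against
#' the true unit direction `p`: the dot-product term aligns the direction and
#' the norm term keeps the prediction near unit length, avoiding an unstable
#' normalization. `l5_angle` has the identical form in 2D against
#' `u = (cos theta, sin theta)`.
#'
#' @param pred Predicted 3-vector (2-vector for `l5_angle`).
#' @param target True offset / unit direction / `(cos, sin)` pair.
#' @return Scalar loss. `l3_offset` is >= 0; `l4_direction`/`l5_angle` are
#'   bounded below by -0.25 (minimum of `1 - c + (c - 1)^2` over the
#'   colinear-norm `c`, attained at `c = 1.5`, not at the unit target — a
#'   documented property of this regression loss, not a defect).
#' @export
l3_offset <- function(pred, target) mean((pred - target)^2)

#' @rdname l3_offset
#' @export
l4_direction <- function(pred, target) {
  1 - sum(pred * target) + (sqrt(sum(pred^2)) - 1)^2
}

#' @rdname l3_offset
#' @export
l5_angle <- function(pred, target) {
  1 - sum(pred * target) + (sqrt(sum(pred^2)) - 1)^2
}

# gradient of 1 - <v,p> + (||v||-1)^2 with respect to v
dir_loss_grad <- function(pred, target) {
  n <- max(sqrt(sum(pred^2)), 1e-9)
  -target + 2 * (n - 1) * pred / n
}

#' VHH class focal loss (L6)
#'
#' Focal loss on the VHH-vs-Fab probability at an occupied cell, with
#' positive-class weight `lam_n`.
#'
#' @param pred Predicted VHH probability.
#' @param ab_class `"fab"` or `"vhh"` (or the 0/1 indicator).
#' @param weights A [loss_weights()].
#' @return Scalar loss.
#' @export
l6_class <- function(pred, ab_class, weights = loss_weights()) {
  y <- if (is.character(ab_class)) as.numeric(ab_class == "vhh") else as.numeric(ab_class)
  sum(focal_loss(pred, y, weights$gamma, weights$lam_n))
}

check_same_geometry <- function(a, b) {
  stopifnot(inherits(a, "pose_grid"), inherits(b, "pose_grid"))
  if (!all(dim(a$channels) == dim(b$channels)))
    stop("prediction and target grids have different shapes")
  invisible(TRUE)
}

#' Total training loss
#'
#' `L_tot = L1 + L2 + lam_s * sum_A (L3 + L4 + L5 + L6)`, where the per-cell
#' sum runs over ground-truth occupied cells only. For a map with no
#' antibodies the Sinkhorn term (which needs a non-empty target measure) is
#' dropped and only L1 remains.
#'
#' @param pred_grid Prediction [pose_grid()] (channels 1 and 10 are
#'   probabilities).
#' @param target_grid Ground-truth [pose_grid()].
#' @param weights A [loss_weights()].
#' @return List with `total` and a `breakdown` of the individual terms
#'   (`l1`, `l2`, and the pose terms summed over antibodies).
#' @export
total_loss <- function(pred_grid, target_grid, weights = loss_weights()) {
  total_loss_impl(pred_grid, target_grid, weights, with_grad = FALSE)[
    c("total", "breakdown")]
}

total_loss_impl <- function(pred_grid, target_grid, weights,
                            with_grad = TRUE, sinkhorn_tol = 1e-9) {
  check_same_geometry(pred_grid, target_grid)
  P <- pred_grid$channels
  G <- target_grid$channels
  grad <- if (with_grad) array(0, dim(P)) else NULL

  l1 <- sum(focal_loss(P[, , , 1], G[, , , 1], weights$gamma, weights$lam))
  if (with_grad)
    grad[, , , 1] <- focal_loss_grad(P[, , , 1], G[, , , 1],
                                     weights$gamma, weights$lam)

  n_ab <- sum(G[, , , 1])
  l2 <- 0
  if (n_ab > 0) {
    sk <- l2_sinkhorn_impl(pred_grid, target_grid, weights, tol = sinkhorn_tol)
    l2 <- sk$value
    if (with_grad) grad[, , , 1] <- grad[, , , 1] + sk$grad_pred
  }

  l3 <- l4 <- l5 <- l6 <- 0
  cells <- occupied_cells(target_grid)
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, ] + 1L
    pv <- P[i[1], i[2], i[3], ]
    gv <- G[i[1], i[2], i[3], ]
    l3 <- l3 + l3_offset(pv[2:4], gv[2:4])
    l4 <- l4 + l4_direction(pv[5:7], gv[5:7])
    l5 <- l5 + l5_angle(pv[8:9], gv[8:9])
    l6 <- l6 + sum(focal_loss(pv[10], gv[10], weights$gamma, weights$lam_n))
    if (with_grad) {
      ls <- weights$lam_s
      grad[i[1], i[2], i[3], 2:4] <- grad[i[1], i[2], i[3], 2:4] +
        ls * 2 * (pv[2:4] - gv[2:4]) / 3
      grad[i[1], i[2], i[3], 5:7] <- grad[i[1], i[2], i[3], 5:7] +
        ls * dir_loss_grad(pv[5:7], gv[5:7])
      grad[i[1], i[2], i[3], 8:9] <- grad[i[1], i[2], i[3], 8:9] +
        ls * dir_loss_grad(pv[8:9], gv[8:9])
      grad[i[1], i[2], i[3], 10] <- grad[i[1], i[2], i[3], 10] +
        ls * focal_loss_grad(pv[10], gv[10], weights$gamma, weights$lam_n)
    }
  }
  total <- l1 + l2 + weights$lam_s * (l3 + l4 + l5 + l6)
  list(total = total,
       breakdown = c(l1 = l1, l2 = l2, l3 = l3, l4 = l4, l5 = l5, l6 = l6),
       grad = grad)
}
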