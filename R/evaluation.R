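#' Match predicted and true antibody centers
#'
#' Minimum-total-distance bipartite assignment (Hungarian algorithm) between
#' predicted and ground-truth centers of mass, followed by thresholding:
#' matched pairs closer than `tp_threshold` are true positives; unmatched or
#' over-threshold predictions are false positives and unmatched or
#' over-threshold ground truths are false negatives. Assignment is done
#' before thresholding, on the full rectangular distance matrix (padded with
#' a large sentinel cost to make it square).
#'
#' @param pred_centers n_pred x 3 matrix of predicted centers (Angstrom);
#'   may have zero rows.
#' @param gt_centers n_gt x 3 matrix of true centers; may have zero rows.
#' @param tp_threshold True-positive distance threshold in Angstrom
#'   (default 10).
#' @return A `match_result` list: `pairs` (data.frame with `pred`, `gt`,
#'   `distance` for every assigned pair), `tp`, `fp`, `fn`.
#' @export
match_detections <- function(pred_centers, gt_centers, tp_threshold = 10) {
  pred_centers <- as_center_matrix(pred_centers)
  gt_centers <- as_center_matrix(gt_centers)
  np <- nrow(pred_centers); ng <- nrow(gt_centers)
  pairs <- data.frame(pred = integer(0), gt = integer(0),
                      distance = numeric(0))
  if (np > 0 && ng > 0) {
    D <- outer(seq_len(np), seq_len(ng), Vectorize(function(i, j)
      sqrt(sum((pred_centers[i, ] - gt_centers[j, ])^2))))
    n <- max(np, ng)
    sentinel <- max(D) * 1e6 + 1e6
    Dp <- matrix(sentinel, n, n)
    Dp[seq_len(np), seq_len(ng)] <- D
    sol <- clue::solve_LSAP(Dp)
    for (i in seq_len(np)) {
      j <- sol[i]
      if (j <= ng)
        pairs <- rbind(pairs, data.frame(pred = i, gt = j,
                                         distance = D[i, j]))
    }
  }
  tp <- sum(pairs$distance < tp_threshold)
  structure(list(pairs = pairs, tp = tp, fp = np - tp, fn = ng - tp,
                 n_pred = np, n_gt = ng, tp_threshold = tp_threshold),
            class = "match_result")
}

as_center_matrix <- function(x) {
  if (is.null(x) || length(x) == 0) return(matrix(0, 0, 3))
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  as.matrix(x)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pred / %d gt: TP %d, FP %d, FN %d (< %g A)\n",
              x$n_pred, x$n_gt, x$tp, x$fp, x$fn, x$tp_threshold))
  invisible(x)
}

#' Detection F1 scores over a set of systems
#'
#' Two aggregations of `F1 = 2 TP / (2 TP + FP + FN)`: `f1_ab` pools counts
#' over all antibodies of all systems, while `f1_sys` averages the
#' per-system F1 so a system with many antibodies does not dominate. A
#' system with no antibodies and no predictions counts as a perfect F1 of 1.
#'
#' @param results List of `match_result`s, one per system.
#' @return List with `f1_ab`, `f1_sys`, `precision`, `recall` (pooled), all
#'   as fractions in `[0, 1]`.
#' @export
f1_scores <- function(results) {
  stopifnot(length(results) >= 1)
  tp <- sum(vapply(results, `[[`, 0, "tp"))
  fp <- sum(vapply(results, `[[`, 0, "fp"))
  fn <- sum(vapply(results, `[[`, 0, "fn"))
  f1_one <- function(tp, fp, fn)
    if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  list(
    f1_ab = f1_one(tp, fp, fn),
    f1_sys = mean(vapply(results, function(r) f1_one(r$tp, r$fp, r$fn), 0)),
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn))
}

#' Angular errors between a predicted and a true pose
#'
#' The direction error is the angle between the predicted and true binding
#' directions; the angle error is the wrapped absolute difference of the
#' residual in-plane angles, mapped to `[0, 180]` degrees.
#'
#' @param pred_pose,gt_pose [ab_pose()]s of a matched pair.
#' @return Named vector: `direction_deg`, `theta_deg`.
#' @export
angular_errors <- function(pred_pose, gt_pose) {
  dt <- sum(pred_pose$direction * gt_pose$direction)
  dir_err <- acos(pmin(pmax(dt, -1), 1)) * 180 / pi
  dth <- abs(pred_pose$angle - gt_pose$angle) %% (2 * pi)
  if (dth > pi) dth <- 2 * pi - dth
  c(direction_deg = dir_err, theta_deg = dth * 180 / pi)
}

#' RMSD between two rigid placements of the same template
#'
#' Root-mean-square deviation between the template atoms transformed by the
#' predicted and the true pose, with no re-superposition (the quantity that
#' measures how far the placed model is from the truth).
#'
#' @param pred_pose,gt_pose [ab_pose()]s.
#' @param template The [ab_template()] both poses place.
#' @return RMSD in Angstrom.
#' @export
placement_rmsd <- function(pred_pose, gt_pose, template) {
  a <- sweep(template$coords %*% t(pred_pose$rotation), 2,
             -pred_pose$translation)
  b <- sweep(template$coords %*% t(gt_pose$rotation), 2,
             -gt_pose$translation)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Evaluate detections against ground truth for a set of systems
#'
#' Convenience wrapper producing the standard report: per-system matching,
#' pooled and per-system F1, and — over true-positive pairs — mean center
#' distance, mean placement RMSD and mean angular errors.
#'
#' @param predictions List (one per system) of detection lists as returned by
#'   [detect_antibodies()].
#' @param truths List (one per system) of ground-truth [ab_pose()] lists.
#' @param templates Named list with `fab` and `vhh` [ab_template()]s used for
#'   the RMSD (defaults to the pseudo templates).
#' @param tp_threshold True-positive distance threshold (Angstrom).
#' @return List with `summary` (named numerics) and `per_system`
#'   (data.frame: n_gt, n_pred, tp, fp, fn, mean_distance, mean_rmsd,
#'   mean_direction_deg, mean_theta_deg).
#' @export
evaluate_detections <- function(predictions, truths,
                                templates = list(fab = make_pseudo_template("fab"),
                                                 vhh = make_pseudo_template("vhh")),
                                tp_threshold = 10) {
  stopifnot(length(predictions) == length(truths))
  results <- vector("list", length(predictions))
  rows <- vector("list", length(predictions))
  dists <- rmsds <- dirs <- thetas <- numeric(0)
  for (s in seq_along(predictions)) {
    pred_poses <- lapply(predictions[[s]], `[[`, "pose")
    pc <- do.call(rbind, lapply(pred_poses, `[[`, "translation"))
    gc_ <- do.call(rbind, lapply(truths[[s]], `[[`, "translation"))
    mr <- match_detections(pc, gc_, tp_threshold)
    results[[s]] <- mr
    sd_ <- sr_ <- sdir <- sth <- numeric(0)
    for (r in seq_len(nrow(mr$pairs))) {
      if (mr$pairs$distance[r] >= tp_threshold) next
      pp <- pred_poses[[mr$pairs$pred[r]]]
      gp <- truths[[s]][[mr$pairs$gt[r]]]
      ae <- angular_errors(pp, gp)
      tmpl <- templates[[gp$ab_class]]
      sd_ <- c(sd_, mr$pairs$distance[r])
      sr_ <- c(sr_, placement_rmsd(pp, gp, tmpl))
      sdir <- c(sdir, ae["direction_deg"])
      sth <- c(sth, ae["theta_deg"])
    }
    dists <- c(dists, sd_); rmsds <- c(rmsds, sr_)
    dirs <- c(dirs, sdir); thetas <- c(thetas, sth)
    rows[[s]] <- data.frame(
      system = s, n_gt = mr$n_gt, n_pred = mr$n_pred, tp = mr$tp,
      fp = mr$fp, fn = mr$fn,
      mean_distance = if (length(sd_)) mean(sd_) else NA_real_,
      mean_rmsd = if (length(sr_)) mean(sr_) else NA_real_,
      mean_direction_deg = if (length(sdir)) mean(sdir) else NA_real_,
      mean_theta_deg = if (length(sth)) mean(sth) else NA_real_)
  }
  f1 <- f1_scores(results)
  list(summary = c(unlist(f1),
                   mean_distance = if (length(dists)) mean(dists) else NA_real_,
                   mean_rmsd = if (length(rmsds)) mean(rmsds) else NA_real_,
                   mean_direction_deg = if (length(dirs)) mean(dirs) else NA_real_,
                   mean_theta_deg = if (length(thetas)) mean(thetas) else NA_real_),
       per_system = do.call(rbind, rows),
       results = results)
}
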