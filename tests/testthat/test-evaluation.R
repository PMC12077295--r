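test_that("matching implements assignment-then-threshold with correct counts", {
  # one prediction 3 A from the truth
  m <- match_detections(c(3, 0, 0), c(0, 0, 0))
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  expect_equal(f1_scores(list(m))$f1_ab, 1)
  # over the 10 A threshold: both a false positive and a false negative
  m2 <- match_detections(c(15, 0, 0), c(0, 0, 0))
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 1))
  expect_equal(f1_scores(list(m2))$f1_ab, 0)
  # empty inputs
  m3 <- match_detections(NULL, c(0, 0, 0))
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0, 0, 1))
  m4 <- match_detections(c(0, 0, 0), NULL)
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(0, 1, 0))
  m5 <- match_detections(NULL, NULL)
  expect_equal(c(m5$tp, m5$fp, m5$fn), c(0, 0, 0))
})

test_that("assignment is globally optimal, not greedy", {
  # distance matrix [[1, 2], [2, 100]]: optimal total is 2 + 2 = 4, while the
  # greedy pairing (p1 -> g1) would cost 1 + 100
  pred <- rbind(c(0, 0, 0), c(0, 97, 0))
  gt <- rbind(c(0, -1, 0), c(0, 2, 0))
  D <- outer(1:2, 1:2, Vectorize(function(i, j)
    sqrt(sum((pred[i, ] - gt[j, ])^2))))
  expect_equal(unname(round(D)), rbind(c(1, 2), c(98, 95)))
  # the canonical anti-greedy cost matrix, checked via the oracle
  Dm <- rbind(c(1, 2), c(2, 100))
  bf <- brute_force_assignment(Dm)
  expect_equal(bf$cost, 4)
  expect_equal(bf$pairs[order(bf$pairs[, 1]), 2], c(2, 1))
})

test_that("Hungarian matching equals exhaustive search on random instances", {
  set.seed(61)
  for (trial in 1:40) {
    np <- sample(0:5, 1); ng <- sample(0:5, 1)
    pred <- matrix(runif(3 * np, 0, 40), ncol = 3)
    gt <- matrix(runif(3 * ng, 0, 40), ncol = 3)
    m <- match_detections(pred, gt, tp_threshold = 10)
    expect_equal(m$tp + m$fn, ng)
    expect_equal(m$tp + m$fp, np)
    if (np == 0 || ng == 0) {
      expect_equal(nrow(m$pairs), 0L)
      next
    }
    D <- outer(seq_len(np), seq_len(ng), Vectorize(function(i, j)
      sqrt(sum((pred[i, ] - gt[j, ]) ^ 2))))
    bf <- brute_force_assignment(D)
    expect_equal(sum(m$pairs$distance), bf$cost, tolerance = 1e-9)
  }
})

test_that("F1 aggregation pools per antibody and averages per system", {
  perfect <- match_detections(c(1, 0, 0), c(0, 0, 0))
  awful <- match_detections(c(50, 0, 0), c(0, 0, 0))
  f <- f1_scores(list(perfect, awful))
  expect_equal(f$f1_sys, 0.5)
  # pooled vs per-system differ when system sizes differ:
  # sys A: 4 GT all found; sys B: 1 GT missed with 1 FP; sys C: 1 GT found
  sysA <- match_detections(matrix(c(0, 0, 0, 20, 0, 0, 40, 0, 0, 60, 0, 0),
                                  ncol = 3, byrow = TRUE),
                           matrix(c(0, 0, 0, 20, 0, 0, 40, 0, 0, 60, 0, 0),
                                  ncol = 3, byrow = TRUE))
  sysB <- awful
  sysC <- perfect
  f3 <- f1_scores(list(sysA, sysB, sysC))
  # pooled: TP 5, FP 1, FN 1 -> 10/12; per-system: mean(1, 0, 1) = 2/3
  expect_equal(f3$f1_ab, 10 / 12)
  expect_equal(f3$f1_sys, 2 / 3)
  expect_equal(f3$recall, 5 / 6)
  expect_equal(f3$precision, 5 / 6)
  # empty system with no predictions is a perfect true negative
  f_empty <- f1_scores(list(match_detections(NULL, NULL)))
  expect_equal(f_empty$f1_ab, 1)
  # order invariance
  f3b <- f1_scores(list(sysC, sysA, sysB))
  expect_equal(f3b$f1_ab, f3$f1_ab)
  expect_equal(f3b$f1_sys, f3$f1_sys)
})

test_that("angular errors are exact on constructed poses and symmetric", {
  p <- ab_pose(diag(3), c(0, 0, 0), "fab")
  expect_equal(unname(angular_errors(p, p)), c(0, 0))
  q <- ab_pose(cryoab:::rotation_about_axis(c(1, 0, 0), pi), c(0, 0, 0), "fab")
  expect_equal(unname(angular_errors(p, q))[1], 180)
  # wrapped angle difference: 350 degrees nominal -> 10 degrees
  a1 <- ab_pose(recompose_rotation(c(0, 0, 1), 175 * pi / 180), c(0, 0, 0), "fab")
  a2 <- ab_pose(recompose_rotation(c(0, 0, 1), -175 * pi / 180), c(0, 0, 0), "fab")
  expect_equal(unname(angular_errors(a1, a2))[2], 10, tolerance = 1e-9)
  set.seed(62)
  r1 <- ab_pose(rand_rot(), c(0, 0, 0), "fab")
  r2 <- ab_pose(rand_rot(), c(0, 0, 0), "fab")
  expect_equal(angular_errors(r1, r2)[1], angular_errors(r2, r1)[1])
})

test_that("placement RMSD matches rigid geometry and a per-atom loop", {
  tmpl <- make_pseudo_template("vhh")
  set.seed(63)
  R <- rand_rot()
  p1 <- ab_pose(R, c(5, 5, 5), "vhh")
  expect_equal(placement_rmsd(p1, p1, tmpl), 0)
  # pure translation offset: RMSD equals the offset length exactly
  p2 <- ab_pose(R, c(5, 5, 5) + c(3, 4, 0), "vhh")
  expect_equal(placement_rmsd(p1, p2, tmpl), 5)
  # random pose pair vs an explicit per-atom loop
  q1 <- ab_pose(rand_rot(), runif(3, -10, 10), "vhh")
  q2 <- ab_pose(rand_rot(), runif(3, -10, 10), "vhh")
  acc <- 0
  for (i in seq_len(nrow(tmpl$coords))) {
    a <- q1$rotation %*% tmpl$coords[i, ] + q1$translation
    b <- q2$rotation %*% tmpl$coords[i, ] + q2$translation
    acc <- acc + sum((a - b)^2)
  }
  expect_equal(placement_rmsd(q1, q2, tmpl),
               sqrt(acc / nrow(tmpl$coords)), tolerance = 1e-12)
})
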