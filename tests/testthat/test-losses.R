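test_that("the focal loss matches its closed form and vanishes at the target", {
  expect_lt(focal_loss(1 - 1e-7, 1), 1e-20)
  expect_lt(focal_loss(1e-7, 0), 1e-20)
  # lam * (1-p)^gamma * log(1/p) at p = 0.5
  expect_equal(focal_loss(0.5, 1, gamma = 4, lam = 30), 30 * 0.5^4 * log(2))
  expect_equal(focal_loss(0.5, 0, gamma = 4), 0.5^4 * log(2))
  # clamping keeps the loss finite at degenerate probabilities
  expect_true(is.finite(focal_loss(0, 1)) && is.finite(focal_loss(1, 0)))
})

test_that("the occupancy focal term equals a brute-force per-cell loop", {
  set.seed(31)
  geom <- grid_geometry(c(4, 3, 2), 8)
  mk <- function(occ, kind) {
    ch <- array(0, c(dim(occ), 10)); ch[, , , 1] <- occ
    pose_grid(ch, geom, kind)
  }
  pred <- mk(array(runif(24, 0.01, 0.99), c(4, 3, 2)), "prediction")
  targ <- mk(array(rbinom(24, 1, 0.2), c(4, 3, 2)), "target")
  w <- loss_weights()
  loop <- 0
  for (i in 1:4) for (j in 1:3) for (k in 1:2)
    loop <- loop + focal_loss(pred$channels[i, j, k, 1],
                              targ$channels[i, j, k, 1], w$gamma, w$lam)
  expect_equal(l1_occupancy(pred, targ, w), loop)
  expect_lt(l1_occupancy(mk(pmin(pmax(targ$channels[, , , 1], 1e-7), 1 - 1e-7),
                            "prediction"), targ, w), 1e-4)
})

test_that("the Sinkhorn term is a debiased symmetric divergence with the d^2 limit", {
  geom <- grid_geometry(c(8, 8, 8), 8)
  mk <- function(occ, kind) {
    ch <- array(0, c(dim(occ), 10)); ch[, , , 1] <- occ
    pose_grid(ch, geom, kind)
  }
  set.seed(32)
  a <- array(runif(512, 0, 1), c(8, 8, 8))
  ga <- mk(a, "prediction")
  ta <- mk(array(as.numeric(a > 0.8), c(8, 8, 8)), "target")
  # identical measures -> zero
  same <- l2_sinkhorn(mk(ta$channels[, , , 1], "prediction"), ta)
  expect_lt(abs(same), 1e-6)
  # symmetry of the divergence
  b <- array(0, c(8, 8, 8)); b[2, 2, 2] <- 1
  gb <- mk(b, "target")
  s1 <- l2_sinkhorn(ga, gb)
  s2 <- cryoab:::l2_sinkhorn_impl(mk(b, "prediction"),
                                  mk(a, "target"), loss_weights())$value
  expect_equal(s1, s2, tolerance = 1e-6)
  # two unit point masses 32 A apart at vanishing blur -> squared distance
  pa <- array(0, c(8, 8, 8)); pa[2, 2, 2] <- 1
  pb <- array(0, c(8, 8, 8)); pb[6, 2, 2] <- 1
  v <- l2_sinkhorn(mk(pa, "prediction"), mk(pb, "target"),
                   loss_weights(ot_blur = 0.5))
  expect_equal(v, 32^2, tolerance = 1e-3)
  # agreement with the dense point-cloud implementation
  ax <- lapply(1:3, function(k) (0:7 + 0.5) * 8)
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  v_grid <- sinkhorn_divergence_grid(a, a * 0 + as.numeric(a > 0.8) + 1e-8,
                                     ax, blur = 8)$value
  v_pts <- sinkhorn_divergence_points(as.numeric(a), pts,
                                      as.numeric(a > 0.8) + 1e-8, pts,
                                      blur = 8)
  expect_equal(v_grid, v_pts, tolerance = 1e-6)
})

test_that("the Sinkhorn term decreases as predicted mass approaches the target", {
  geom <- grid_geometry(c(10, 4, 4), 8)
  mk <- function(occ, kind) {
    ch <- array(0, c(dim(occ), 10)); ch[, , , 1] <- occ
    pose_grid(ch, geom, kind)
  }
  t_ <- array(0, c(10, 4, 4)); t_[9, 2, 2] <- 1
  targ <- mk(t_, "target")
  vals <- vapply(1:5, function(i) {
    p <- array(0, c(10, 4, 4)); p[i, 2, 2] <- 1
    l2_sinkhorn(mk(p, "prediction"), targ)
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("pose and class terms match their formulas", {
  p <- c(0, 0, 1)
  expect_equal(l4_direction(p, p), 0)
  expect_equal(l5_angle(c(1, 0), c(1, 0)), 0)
  expect_equal(l4_direction(-p, p), 2)
  expect_equal(l4_direction(2 * p, p), 0)  # documented non-unique minimum
  expect_equal(l3_offset(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(l3_offset(c(2, 2, 3), c(1, 2, 4)), 2 / 3)
  # lower bound of the direction losses: 1 - c + (c - 1)^2 >= -1/4
  set.seed(33)
  for (i in 1:200) {
    v <- rnorm(3) * runif(1, 0, 3)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    expect_gte(l4_direction(v, u), -0.25 - 1e-12)
  }
  w <- loss_weights()
  expect_equal(w$lam_n, 2.5)
  expect_lt(l6_class(1 - 1e-7, "vhh", w), 1e-20)
  expect_equal(l6_class(0.5, "fab", w), 0.5^4 * log(2))
  expect_equal(l6_class(0.5, "vhh", w), 2.5 * 0.5^4 * log(2))
})

test_that("the total loss recombines its terms and vanishes at a perfect prediction", {
  set.seed(34)
  geom <- grid_geometry(c(5, 5, 5), 8)
  poses <- list(ab_pose(rand_rot(), c(12, 9, 22), "fab"),
                ab_pose(rand_rot(), c(30, 30, 11), "vhh"))
  targ <- encode_poses(poses, geom)
  # perfect prediction: pose channels copied, probabilities clamped
  ch <- targ$channels
  ch[, , , 1] <- pmin(pmax(ch[, , , 1], 1e-7), 1 - 1e-7)
  ch[, , , 10] <- pmin(pmax(ch[, , , 10], 1e-7), 1 - 1e-7)
  perfect <- pose_grid(ch, geom, "prediction")
  tl <- total_loss(perfect, targ)
  # the clamp floor (1e-7) leaves a whiff of transportable background mass,
  # so the Sinkhorn term is ~1e-4 Angstrom^2 rather than exactly 0
  expect_lt(abs(tl$total), 1e-3)
  expect_true(all(abs(tl$breakdown) < 1e-3))

  # random prediction: total equals the hand-summed terms
  chr <- array(rnorm(prod(dim(ch))), dim(ch))
  chr[, , , 1] <- runif(125, 0.01, 0.99)
  chr[, , , 10] <- runif(125, 0.01, 0.99)
  pred <- pose_grid(chr, geom, "prediction")
  w <- loss_weights()
  tl2 <- total_loss(pred, targ, w)
  hand <- l1_occupancy(pred, targ, w) + l2_sinkhorn(pred, targ, w)
  for (p in poses) {
    ci <- ab_pose(p$rotation, p$translation, p$ab_class, geometry = geom)$cell_index + 1L
    pv <- chr[ci[1], ci[2], ci[3], ]
    hand <- hand + w$lam_s *
      (l3_offset(pv[2:4], targ$channels[ci[1], ci[2], ci[3], 2:4]) +
         l4_direction(pv[5:7], p$direction) +
         l5_angle(pv[8:9], c(cos(p$angle), sin(p$angle))) +
         l6_class(pv[10], p$ab_class, w))
  }
  expect_equal(tl2$total, hand, tolerance = 1e-10)

  # lam_s = 0 reduces the total to L1 + L2
  w0 <- loss_weights(lam_s = 0)
  tl0 <- total_loss(pred, targ, w0)
  expect_equal(tl0$total, l1_occupancy(pred, targ, w0) +
                 l2_sinkhorn(pred, targ, w0), tolerance = 1e-10)
})

test_that("the total loss gradient matches finite differences", {
  set.seed(35)
  geom <- grid_geometry(c(4, 4, 4), 8)
  poses <- list(ab_pose(rand_rot(), c(12, 9, 22), "vhh"))
  targ <- encode_poses(poses, geom)
  ch <- array(rnorm(4 * 4 * 4 * 10, sd = 0.5), c(4, 4, 4, 10))
  ch[, , , 1] <- runif(64, 0.05, 0.95)
  ch[, , , 10] <- runif(64, 0.05, 0.95)
  pred <- pose_grid(ch, geom, "prediction")
  w <- loss_weights()
  li <- cryoab:::total_loss_impl(pred, targ, w, with_grad = TRUE,
                                 sinkhorn_tol = 1e-12)
  eps <- 1e-6
  idx <- c(sample(64, 3),                       # occupancy channel entries
           64 * 9 + sample(64, 2),              # class channel
           sample(64 * 8, 3) + 64)              # pose channels
  for (i in idx) {
    chp <- ch; chp[i] <- ch[i] + eps
    lp <- cryoab:::total_loss_impl(pose_grid(chp, geom, "prediction"), targ,
                                   w, FALSE, 1e-12)$total
    chp[i] <- ch[i] - eps
    lm <- cryoab:::total_loss_impl(pose_grid(chp, geom, "prediction"), targ,
                                   w, FALSE, 1e-12)$total
    fd <- (lp - lm) / (2 * eps)
    expect_equal(li$grad[i], fd, tolerance = 1e-3)
  }
})
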