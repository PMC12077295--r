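test_that("rotation decomposition is exact on axis-aligned cases and round-trips", {
  d <- decompose_rotation(diag(3))
  expect_equal(d$direction, c(0, 0, 1))
  expect_equal(d$angle, 0)

  Rz <- cryoab:::rotation_about_axis(c(0, 0, 1), 0.3)
  d <- decompose_rotation(Rz)
  expect_equal(d$direction, c(0, 0, 1))
  expect_equal(d$angle, 0.3)

  expect_equal(recompose_rotation(c(0, 0, 1), 0), diag(3))
  phi <- -1.2
  expect_equal(recompose_rotation(c(0, 0, 1), phi),
               cryoab:::rotation_about_axis(c(0, 0, 1), phi))

  set.seed(21)
  worst <- 0
  for (i in 1:300) {
    R <- rand_rot()
    dd <- decompose_rotation(R)
    expect_gte(dd$angle, -pi)
    expect_lt(dd$angle, pi)
    worst <- max(worst, max(abs(recompose_rotation(dd$direction, dd$angle) - R)))
  }
  expect_lt(worst, 1e-9)
})

test_that("the antipodal direction uses the fixed 180-degree convention", {
  R <- recompose_rotation(c(0, 0, -1), 0)
  expect_equal(as.numeric(R %*% c(0, 0, 1)), c(0, 0, -1))
  expect_equal(det(R), 1)
  # decompose still maps u_z to -u_z for rotations near the antipode
  Rn <- cryoab:::rotation_about_axis(c(1, 0, 0), pi)
  dd <- decompose_rotation(Rn)
  expect_equal(dd$direction, c(0, 0, -1))
  expect_equal(as.numeric(recompose_rotation(dd$direction, dd$angle) %*%
                            c(0, 0, 1)), c(0, 0, -1))
})

test_that("pose encoding writes the documented channels at the owner cell", {
  geom <- grid_geometry(c(4, 4, 4), cell_size = 8, origin = c(0, 0, 0))
  p <- ab_pose(diag(3), c(17, 3, 5), "fab", geometry = geom)
  expect_equal(p$cell_index, c(2L, 0L, 0L))
  expect_equal(p$local_offset, c(1, 3, 5))

  tg <- encode_poses(list(p), geom)
  expect_equal(sum(tg$channels[, , , 1]), 1)
  expect_equal(tg$channels[3, 1, 1, 1], 1)
  expect_equal(tg$channels[3, 1, 1, 2:4], c(1, 3, 5))
  expect_equal(tg$channels[3, 1, 1, 5:7], c(0, 0, 1))
  expect_equal(tg$channels[3, 1, 1, 8:9], c(1, 0))
  expect_equal(tg$channels[3, 1, 1, 10], 0)

  empty <- encode_poses(list(), geom)
  expect_true(all(empty$channels == 0))

  # occupancy counts poses
  set.seed(22)
  poses <- lapply(1:3, function(i)
    ab_pose(rand_rot(), c(4 + 8 * (i - 1) * c(1, 0, 0)) + c(2, 3, 4),
            sample(c("fab", "vhh"), 1)))
  tg3 <- encode_poses(poses, geom)
  expect_equal(sum(tg3$channels[, , , 1]), 3)

  # a colliding pair cannot be represented
  q1 <- ab_pose(diag(3), c(10, 10, 10), "fab")
  q2 <- ab_pose(diag(3), c(12, 12, 12), "fab")
  expect_error(encode_poses(list(q1, q2), geom), "same grid cell")
})

test_that("encode/decode round trip recovers pose, class and rotation exactly", {
  geom <- grid_geometry(c(6, 6, 6), cell_size = 8, origin = c(-8, 4, 0))
  set.seed(23)
  for (i in 1:25) {
    R <- rand_rot()
    t_ <- c(runif(1, -7, 39), runif(1, 5, 51), runif(1, 1, 47))
    cls <- sample(c("fab", "vhh"), 1)
    p <- ab_pose(R, t_, cls)
    tg <- encode_poses(list(p), geom)
    q <- decode_cell(tg, cryoab:::occupied_cells(tg)[1, ])
    expect_lt(max(abs(q$rotation - p$rotation)), 1e-9)
    expect_lt(max(abs(q$translation - p$translation)), 1e-9)
    expect_identical(q$ab_class, cls)
  }
})

test_that("cell decoding applies the documented normalization and class rule", {
  geom <- grid_geometry(c(2, 2, 2), cell_size = 8)
  ch <- array(0, c(2, 2, 2, 10))
  ch[1, 1, 1, 1] <- 1
  ch[1, 1, 1, 2:4] <- c(2, 2, 2)
  ch[1, 1, 1, 5:7] <- c(0, 0, 2)      # direction gets normalized
  ch[1, 1, 1, 8:9] <- c(1, 0)
  ch[1, 1, 1, 10] <- 0.7              # > 0.5 -> VHH
  pg <- pose_grid(ch, geom, "prediction")
  q <- decode_cell(pg, c(0, 0, 0))
  expect_equal(q$direction, c(0, 0, 1))
  expect_identical(q$ab_class, "vhh")
  ch[1, 1, 1, 10] <- 0.3
  q2 <- decode_cell(pose_grid(ch, geom, "prediction"), c(0, 0, 0))
  expect_identical(q2$ab_class, "fab")
  ch[1, 1, 1, 5:7] <- 0
  expect_error(decode_cell(pose_grid(ch, geom, "prediction"), c(0, 0, 0)),
               "degenerate")
})

test_that("encoding is translation covariant", {
  set.seed(24)
  delta <- c(13.5, -7.25, 2)
  geom1 <- grid_geometry(c(5, 5, 5), 8, origin = c(0, 0, 0))
  geom2 <- grid_geometry(c(5, 5, 5), 8, origin = delta)
  poses <- lapply(1:3, function(i)
    ab_pose(rand_rot(), runif(3, 5, 35), sample(c("fab", "vhh"), 1)))
  shifted <- lapply(poses, function(p)
    ab_pose(p$rotation, p$translation + delta, p$ab_class))
  t1 <- encode_poses(poses, geom1)
  t2 <- encode_poses(shifted, geom2)
  expect_equal(t1$channels, t2$channels)
})

test_that("template superposition recovers known transforms with outlier rejection", {
  tmpl <- make_pseudo_template("fab")
  # exact self-fit
  fit0 <- superpose_template(tmpl, tmpl$coords)
  expect_lt(max(abs(fit0$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(fit0$translation)), 1e-9)
  expect_lt(fit0$rmsd, 1e-9)

  set.seed(25)
  for (i in 1:5) {
    R0 <- rand_rot()
    T0 <- runif(3, -30, 30)
    moved <- sweep(tmpl$coords %*% t(R0), 2, -T0)
    fit <- superpose_template(tmpl, moved)
    expect_lt(max(abs(fit$rotation - R0)), 1e-9)
    expect_lt(max(abs(fit$translation - T0)), 1e-9)
    expect_lt(fit$rmsd, 1e-12)
  }

  # gross outliers (mimicking divergent CDR loops) are rejected
  moved <- sweep(tmpl$coords %*% t(rand_rot()), 2, -c(5, 5, 5))
  noisy <- moved + matrix(rnorm(length(moved), 0, 0.2), ncol = 3)
  noisy[1:8, ] <- noisy[1:8, ] + 25
  fit <- superpose_template(tmpl, noisy)
  expect_lt(fit$rmsd, 1)
  expect_lte(fit$n_matched, nrow(tmpl$coords) - 8)

  expect_error(superpose_template(tmpl, tmpl$coords[1:10, ], min_matched = 50),
               "alignment failure|matched")
})

test_that("sequence-based residue pairing drives the superposition", {
  set.seed(26)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- 80
  seq1 <- sample(aas, n, replace = TRUE)
  coords <- matrix(runif(3 * n, -20, 20), ncol = 3)
  tmpl <- ab_template(coords, "vhh", chain = rep("N", n), sequence = seq1)
  R0 <- rand_rot(); T0 <- c(4, -2, 9)
  # target shares residues 11..80, with 5 extra leading residues of its own
  extra <- 5
  tseq <- c(sample(aas, extra, replace = TRUE), seq1[11:n])
  tcoords <- rbind(matrix(runif(3 * extra, 40, 60), ncol = 3),
                   sweep(tmpl$coords[11:n, ] %*% t(R0), 2, -T0))
  fit <- superpose_template(tmpl,
                            list(coords = tcoords, sequence = tseq,
                                 chain = rep("N", nrow(tcoords))),
                            min_matched = 50)
  expect_gte(fit$n_matched, 60)
  expect_lt(max(abs(fit$rotation - R0)), 1e-6)
  expect_lt(fit$rmsd, 1e-6)
})
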