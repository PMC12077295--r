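test_that("prediction obeys the fully convolutional shape contract", {
  model <- new_detector(tiny_cfg(), seed = 1)
  g <- density_grid(array(runif(16^3), c(16, 16, 16)), voxel = 2)
  pg <- predict_grid(model, g)
  expect_equal(dim(pg$channels), c(4L, 4L, 4L, 10L))
  expect_equal(pg$geometry$cell_size, 8)
  expect_equal(pg$geometry$origin, g$origin)
  # non-multiple extents are padded internally and cropped back
  g2 <- density_grid(array(runif(18 * 22 * 16), c(18, 22, 16)), voxel = 2,
                     origin = c(4, 4, 4))
  pg2 <- predict_grid(model, g2)
  expect_equal(dim(pg2$channels)[1:3], c(5L, 6L, 4L))
  expect_equal(pg2$geometry$origin, c(4, 4, 4))
  # sigmoid channels lie strictly inside (0, 1)
  for (ch in c(1, 10)) {
    expect_true(all(pg2$channels[, , , ch] > 0))
    expect_true(all(pg2$channels[, , , ch] < 1))
  }
  # too-small input
  tiny <- density_grid(array(0, c(4, 4, 4)), voxel = 2)
  expect_error(predict_grid(model, tiny), "too small")
})

test_that("prediction on an all-zero map is finite", {
  model <- new_detector(tiny_cfg(), seed = 2)
  g <- density_grid(array(0, c(16, 16, 16)), voxel = 2)
  pg <- predict_grid(model, g)
  expect_true(all(is.finite(pg$channels)))
})

test_that("the occupancy response moves with a stride-aligned translation", {
  # overfit a tiny model to one blob so the response is localized, then
  # shift the map content by one stride and check the argmax cell follows
  ex <- tiny_example(seed = 41, extent = 46)   # 24^3 voxels -> 6^3 cells
  model <- new_detector(unet_config(depth = 3, base_channels = 4), seed = 3)
  model <- train_detector(model, list(ex), epochs = 40, lr = 3e-3, seed = 4,
                          augment = FALSE)
  v <- ex$grid$values
  d <- dim(v)
  shifted <- array(0, d)
  shifted[5:d[1], , ] <- v[1:(d[1] - 4), , ]
  am <- function(g) {
    occ <- predict_grid(model, g)$channels[, , , 1]
    which(occ == max(occ), arr.ind = TRUE)[1, ]
  }
  a1 <- am(ex$grid)
  a2 <- am(density_grid(shifted, ex$grid$voxel, ex$grid$origin))
  expect_equal(unname(a2 - a1), c(1, 0, 0))
})

test_that("augmentation preserves content under the identity and obeys the group law", {
  ex <- tiny_example(seed = 42)
  id <- augment_example(ex$grid, ex$target, rot_index = 1,
                        crop_cells = matrix(0L, 3, 2))
  expect_equal(id$grid$values, ex$grid$values)
  expect_equal(id$target$channels, ex$target$channels)

  # two 90-degree z rotations equal one 180-degree z rotation
  r90 <- augment_example(ex$grid, ex$target, rot_index = 2,
                         crop_cells = matrix(0L, 3, 2))
  r90x2 <- augment_example(r90$grid, r90$target, rot_index = 2,
                           crop_cells = matrix(0L, 3, 2))
  r180 <- augment_example(ex$grid, ex$target, rot_index = 3,
                          crop_cells = matrix(0L, 3, 2))
  expect_equal(r90x2$grid$values, r180$grid$values)
  expect_equal(r90x2$target$channels, r180$target$channels, tolerance = 1e-9)
})

test_that("augmented targets still decode into valid poses", {
  spec <- synthetic_spec(extent = 62, n_antibodies = 2, sigma = 4,
                         noise_sd = 0.05, n_decoys = 0, boundary_pad = 16,
                         min_separation = 20)
  sim <- simulate_map(spec, seed = 43)
  geom <- cryoab:::geometry_for_grid(sim$grid, 4L)
  targ <- encode_poses(sim$poses, geom)
  set.seed(44)
  for (i in 1:8) {
    aug <- augment_example(sim$grid, targ)
    for (p in aug$poses) {
      expect_lt(max(abs(t(p$rotation) %*% p$rotation - diag(3))), 1e-9)
      expect_lt(max(abs(recompose_rotation(p$direction, p$angle) -
                          p$rotation)), 1e-9)
    }
    # re-decoding the augmented grid reproduces the surviving poses
    dec <- cryoab:::decode_target(aug$target)
    expect_equal(length(dec), length(aug$poses))
  }
})

test_that("training reduces the loss, is seed-deterministic, and freezes at lr 0", {
  ex <- tiny_example(seed = 45)
  cfg <- unet_config(depth = 3, base_channels = 4)
  m0 <- new_detector(cfg, seed = 5)
  w <- loss_weights()
  l0 <- cryoab:::train_step(m0$params, cfg, ex$grid, ex$target, w, 1e-4)$loss
  m1 <- train_detector(m0, list(ex), epochs = 25, lr = 3e-3, seed = 6,
                       augment = FALSE)
  lT <- tail(m1$history$train, 1)
  expect_lt(lT, l0)

  h1 <- train_detector(m0, list(ex), epochs = 3, lr = 1e-3, seed = 7)$history
  h2 <- train_detector(m0, list(ex), epochs = 3, lr = 1e-3, seed = 7)$history
  expect_identical(h1$train, h2$train)

  h0 <- train_detector(m0, list(ex), epochs = 3, lr = 0, seed = 8,
                       augment = FALSE)$history
  expect_equal(diff(h0$train), c(0, 0), tolerance = 1e-12)
})

test_that("checkpoints round trip through disk", {
  model <- new_detector(tiny_cfg(), seed = 9)
  p <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(model, p)
  m2 <- load_checkpoint(p)
  expect_equal(m2$params, model$params)
  expect_equal(unclass(m2$cfg), unclass(model$cfg))
  g <- density_grid(array(runif(16^3), c(16, 16, 16)), voxel = 2)
  expect_equal(predict_grid(m2, g)$channels, predict_grid(model, g)$channels)
})
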