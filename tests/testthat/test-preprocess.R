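test_that("standardize pads small frames and crops large ones, centred", {
  cfg <- preprocess_config(target_inplane = 320L, slab_size = 256L)
  vox <- array(runif(256 * 256 * 4, 1, 255), c(256, 256, 4))
  st <- standardize_stack(make_stack(vox), cfg)
  expect_identical(dim(st$stack$voxels), c(320L, 320L, 4L))
  expect_equal(st$stack$voxels[33:288, 33:288, ], vox, ignore_attr = TRUE)
  expect_true(all(st$stack$voxels[1:32, , ] == 0))

  big <- array(0, c(512, 512, 2))
  big[200:300, 220:280, ] <- 7
  stb <- standardize_stack(make_stack(big), cfg)
  expect_identical(dim(stb$stack$voxels), c(320L, 320L, 2L))
  expect_equal(sum(stb$stack$voxels == 7), sum(big == 7))

  same <- array(runif(320 * 320 * 2), c(320, 320, 2))
  expect_equal(standardize_stack(make_stack(same), cfg)$stack$voxels, same,
               ignore_attr = TRUE)
})

test_that("standardize transforms the paired mask identically and protects foreground", {
  cfg <- preprocess_config(target_inplane = 64L, slab_size = 32L)
  vox <- array(runif(48 * 48 * 3, 1, 255), c(48, 48, 3))
  msk <- array(0L, c(48, 48, 3)); msk[20:30, 20:30, 2] <- 1L
  st <- standardize_stack(make_stack(vox), cfg, make_mask(msk))
  expect_equal(sum(st$mask$voxels), sum(msk))

  big <- array(1, c(100, 100, 2))
  edge_mask <- array(0L, c(100, 100, 2)); edge_mask[1:5, 1:5, 1] <- 1L
  expect_error(standardize_stack(make_stack(big), cfg, make_mask(edge_mask)),
               "fully included")
  ok_mask <- array(0L, c(100, 100, 2)); ok_mask[40:60, 40:60, 1] <- 1L
  st2 <- standardize_stack(make_stack(big), cfg, make_mask(ok_mask))
  expect_equal(sum(st2$mask$voxels), sum(ok_mask))
})

test_that("blank-frame filter is inclusive at the threshold and monotone", {
  cfg <- preprocess_config(target_inplane = 320L, slab_size = 256L)
  vox <- array(0, c(320, 320, 3))
  vox[, , 2][seq_len(20480)] <- 9          # exactly 20.0% non-zero
  vox[, , 3][seq_len(40000)] <- 9
  st <- make_stack(vox)
  expect_identical(filter_blank_frames(st, cfg), 2:3)
  expect_identical(
    filter_blank_frames(st, preprocess_config(320L, 256L, 0)), 1:3)
  # monotone: higher threshold keeps a subset
  thresholds <- c(0, 0.1, 0.2, 0.3, 0.5)
  kept <- lapply(thresholds, function(th)
    filter_blank_frames(st, preprocess_config(320L, 256L, th)))
  for (i in seq_len(length(kept) - 1))
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  # idempotent given the already-filtered substack
  k <- filter_blank_frames(st, cfg)
  st2 <- make_stack(vox[, , k, drop = FALSE])
  expect_identical(filter_blank_frames(st2, cfg), seq_along(k))
})

test_that("slabs clamp at sweep edges and interpolate exactly on constants", {
  cfg <- preprocess_config(target_inplane = 64L, slab_size = 32L)
  vox <- array(0, c(64, 64, 4))
  for (k in 1:4) vox[, , k] <- k * 10
  st <- make_stack(vox)
  sl <- make_slab(st, 1, cfg)
  expect_equal(unique(as.vector(sl$image[, , 1])), 10)  # clamped z-1 -> 1
  expect_equal(unique(as.vector(sl$image[, , 2])), 10)
  expect_equal(unique(as.vector(sl$image[, , 3])), 20)
  sl4 <- make_slab(st, 4, cfg)
  expect_equal(unique(as.vector(sl4$image[, , 3])), 40)  # clamped z+1 -> 4
  expect_error(make_slab(st, 9, cfg), "outside the stack")
  expect_identical(dim(sl$image), c(32L, 32L, 3L))
})

test_that("mask resampling round-trips with high Dice on phantom masks", {
  r <- tiny_phantom()
  cfg <- preprocess_config(target_inplane = 64L, slab_size = 48L)
  fg_frames <- which(apply(r$mask$voxels, 3, sum) > 200)
  dices <- vapply(fg_frames, function(z) {
    down <- sonotkv:::cpp_resize_nearest(r$mask$voxels[, , z] + 0, 48L, 48L)
    up <- sonotkv:::cpp_resize_nearest(down, 64L, 64L)
    a <- r$mask$voxels[, , z]
    2 * sum(up == 1 & a == 1) / (sum(up) + sum(a))
  }, numeric(1))
  expect_gte(mean(dices), 0.95)
})
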