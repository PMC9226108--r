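test_that("the default architecture matches the published schedule", {
  cfg <- unet_config()
  m <- build_unet(cfg)
  enc <- m$summary[m$summary$stage == "encoder", ]
  expect_equal(enc$out_channels, c(32, 64, 128, 256, 512, 1024))
  expect_equal(enc$kernel, c(7, 7, 5, 5, 3, 3))
  dec <- m$summary[m$summary$stage == "decoder", ]
  expect_equal(dec$kernel[order(dec$level)], c(7, 7, 5, 5, 3))
  # parameter count sits in the band around the ~18M comparison anchor
  expect_gte(m$n_params, 14e6)
  expect_lte(m$n_params, 22e6)
})

test_that("incompatible slab sizes are rejected", {
  expect_error(build_unet(unet_config(levels = 6L, slab_size = 100L)),
               "divisible")
})

test_that("network output is a probability map of the right shape", {
  cfg <- unet_config(levels = 3L, base_filters = 2L, slab_size = 16L,
                     seed = 2)
  m <- build_unet(cfg)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  p <- sonotkv:::unet_forward(m, x)$prob
  expect_identical(dim(p), c(16L, 16L, 1L, 2L))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("dice loss matches hand-worked values and symmetry", {
  a <- array(0, c(4, 4)); a[1:2, 1:2] <- 1
  expect_lt(dice_loss(a, a), 1e-6)
  b <- array(0, c(4, 4)); b[3:4, 3:4] <- 1
  expect_gt(dice_loss(a, b), 1 - 1e-6)
  # 4-px prediction overlapping a 4-px target in exactly 2 px
  p <- array(0, c(4, 4)); p[1:2, 1:2] <- 1
  t <- array(0, c(4, 4)); t[2:3, 1:2] <- 1
  expect_equal(dice_loss(p, t), 0.5, tolerance = 1e-6)
  expect_equal(dice_loss(p, t), dice_loss(t, p), tolerance = 1e-12)
  expect_error(dice_loss(array(0, c(2, 2)), array(0, c(3, 3))), "differ")
})

test_that("dice loss complements the metric panel's DSC on binary masks", {
  set.seed(7)
  for (i in 1:5) {
    p <- random_mask_array(c(6, 6, 4), 0.4)
    r <- random_mask_array(c(6, 6, 4), 0.4)
    dsc <- overlap_metrics(confusion_counts(p, r))$dsc
    expect_equal(1 - dice_loss(p, r), dsc, tolerance = 1e-4)
  }
})

test_that("analytic gradients agree with central differences", {
  set.seed(12)
  cfg <- unet_config(levels = 2L, base_filters = 2L, slab_size = 8L,
                     seed = 5)
  m <- build_unet(cfg)
  x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.4), c(8, 8, 1, 2))
  fwd <- sonotkv:::unet_forward(m, x, training = TRUE)
  g <- sonotkv:::unet_backward(m, fwd, sonotkv:::dice_loss_grad(fwd$prob, y))
  lossfn <- function(model) {
    f <- sonotkv:::unet_forward(model, x, training = TRUE)
    dice_loss(f$prob, y)
  }
  eps <- 1e-5
  for (nm in names(g)) {
    i <- sample(length(m$par[[nm]]), 1)
    m2 <- m
    m2$par[[nm]][i] <- m$par[[nm]][i] + eps
    l1 <- lossfn(m2)
    m2$par[[nm]][i] <- m$par[[nm]][i] - eps
    l0 <- lossfn(m2)
    num <- (l1 - l0) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                 label = sprintf("grad of %s", nm))
  }
})

test_that("training overfits a single phantom slab", {
  r <- tiny_phantom()
  cfgp <- preprocess_config(target_inplane = 64L, slab_size = 32L)
  std <- standardize_stack(r$stack, cfgp, r$mask)
  z <- which.max(apply(std$mask$voxels, 3, sum))
  sl <- make_slab(std$stack, z, cfgp, std$mask)
  sample1 <- list(x = sl$image / 255, y = sl$mask, patient_id = "p1")
  cfg <- unet_config(levels = 4L, base_filters = 4L, slab_size = 32L,
                     learning_rate = 5e-3, epochs = 200L, batch_size = 1L,
                     seed = 3)
  m <- train_unet(build_unet(cfg), list(sample1))
  expect_gte(tail(m$curves$train_dice, 1), 0.95)
  expect_equal(nrow(m$curves), 200L)
})

test_that("an empty training set and patient-overlapping splits are rejected", {
  cfg <- unet_config(levels = 2L, base_filters = 2L, slab_size = 8L)
  m <- build_unet(cfg)
  expect_error(train_unet(m, list()), "empty")
  s <- list(x = array(0.5, c(8, 8, 3)), y = matrix(0L, 8, 8),
            patient_id = "p1")
  expect_error(train_unet(m, list(s), list(s)), "both training and validation")
})

test_that("pretrained weights give a head start over random initialization", {
  r <- tiny_phantom()
  cfgp <- preprocess_config(target_inplane = 64L, slab_size = 32L)
  std <- standardize_stack(r$stack, cfgp, r$mask)
  zs <- order(apply(std$mask$voxels, 3, sum), decreasing = TRUE)[1:4]
  samples <- lapply(zs, function(z) {
    sl <- make_slab(std$stack, z, cfgp, std$mask)
    list(x = sl$image / 255, y = sl$mask, patient_id = "p1")
  })
  cfg <- unet_config(levels = 4L, base_filters = 4L, slab_size = 32L,
                     learning_rate = 2e-3, epochs = 40L, batch_size = 4L,
                     seed = 3)
  trained <- train_unet(build_unet(cfg), samples)
  ck <- tempfile(fileext = ".rds")
  save_unet(trained, ck)
  val <- lapply(samples, function(s) { s$patient_id <- "p2"; s })
  cfg2 <- cfg; cfg2$pretrained_weights_path <- ck; cfg2$seed <- 99L
  warm <- build_unet(cfg2)
  cfg3 <- cfg; cfg3$seed <- 99L
  cold <- build_unet(cfg3)
  d_warm <- sonotkv:::eval_dice(warm, val, 4L)
  d_cold <- sonotkv:::eval_dice(cold, val, 4L)
  expect_gte(d_warm, d_cold)
  unlink(ck)
})

test_that("stack prediction honours the binarization threshold and blank filter", {
  cfgp <- preprocess_config(target_inplane = 24L, slab_size = 16L,
                            nonzero_frame_threshold = 0.2)
  vox <- array(0, c(24, 24, 5))
  vox[, , 2:4] <- 120
  st <- make_stack(vox)
  cfg <- unet_config(levels = 2L, base_filters = 2L, slab_size = 16L,
                     seed = 1)
  m <- build_unet(cfg)
  m$par[["final.w"]][] <- 0
  m$par[["final.b"]] <- -50          # constant ~zero probability
  pr <- predict_stack(m, st, cfgp)
  expect_identical(pr$kept, 2:4)
  expect_equal(mask_volume(pr$mask), 0)
  expect_true(all(pr$prob[, , c(1, 5)] == 0))
  m$cfg$binarize_threshold <- 0      # upper envelope: all kept frames on
  pr0 <- predict_stack(m, st, cfgp)
  expect_true(all(pr0$mask$voxels[, , 2:4] == 1))
  expect_true(all(pr0$mask$voxels[, , c(1, 5)] == 0))
  # determinism of prediction
  pr2 <- predict_stack(m, st, cfgp)
  expect_identical(pr0$prob, pr2$prob)
  expect_error(predict_stack(m, make_stack(array(0, c(30, 30, 4))), cfgp),
               "geometry")
})
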