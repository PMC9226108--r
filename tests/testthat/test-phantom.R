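test_that("sampled specs are deterministic and validated", {
  s1 <- sample_spec(7, "centered")
  s2 <- sample_spec(7, "centered")
  expect_identical(s1, s2)
  s3 <- sample_spec(8, "centered")
  expect_false(identical(s1, s3))
  expect_error(sample_spec(7, "impossible"), "unknown difficulty")
  expect_error(phantom_spec(axes_mm = c(-1, 10, 10)), "positive")
  expect_error(phantom_spec(n_frames = 2), "at least 3")
  expect_error(phantom_spec(in_plane_size = 100), "in_plane_size")
})

test_that("sampled gains stay inside the clinical export range", {
  for (difficulty in c("centered", "low_contrast", "small_fov", "oversized")) {
    gains <- vapply(1:25, function(s)
      sample_spec(s, difficulty)$gain, numeric(1))
    expect_true(all(gains >= 0.54 & gains <= 0.68), info = difficulty)
  }
  lc <- vapply(1:25, function(s) sample_spec(s, "low_contrast")$gain,
               numeric(1))
  expect_true(all(lc <= 0.56))
})

test_that("oversized kidneys exceed the sector depth and get clipped", {
  spec <- sample_spec(5, "oversized", in_plane_size = 64L, n_frames = 24L,
                      spacing_mm = c(3, 3, 4))
  expect_gt(2 * spec$axes_mm[1], spec$sector_fov$depth_mm)
  r <- render_phantom(spec)
  # unclipped reference: same kidney with an enveloping FOV
  big <- spec
  big$sector_fov <- list(apex_mm = -15, width_deg = 179, depth_mm = 1000)
  rb <- render_phantom(big)
  expect_lt(mask_volume(r$mask), mask_volume(rb$mask))
  # clipping never adds foreground
  expect_true(all(r$mask$voxels <= rb$mask$voxels))
})

test_that("rendering is deterministic and geometrically sound", {
  r <- tiny_phantom()
  r2 <- render_phantom(sample_spec(3, "centered", in_plane_size = 64L,
                                   n_frames = 24L, spacing_mm = c(3, 3, 4)))
  expect_identical(r$stack$voxels, r2$stack$voxels)
  expect_identical(r$mask$voxels, r2$mask$voxels)
  expect_true(all(r$stack$voxels >= 0 & r$stack$voxels <= 255))
  expect_true(all(r$mask$voxels %in% c(0L, 1L)))
  expect_identical(dim(r$mask$voxels), dim(r$stack$voxels))
})

test_that("a 10 mm sphere voxelizes to within 2% of 4.18879 mL", {
  spec <- phantom_spec(axes_mm = c(10, 10, 10), center_mm = c(60, 0, 0),
                       cysts = list(), spacing_mm = c(1, 1, 1),
                       in_plane_size = 128L, n_frames = 48L,
                       speckle_scale = 0, seed = 1)
  r <- render_phantom(spec)
  expect_equal(r$analytic_volume_mL, 4 / 3 * pi * 10^3 / 1000,
               tolerance = 1e-12)
  expect_lt(abs(mask_volume(r$mask) - 4.18879) / 4.18879, 0.02)
})

test_that("voxelized volume converges to the analytic volume as spacing shrinks", {
  rel_err <- vapply(c(2, 1, 0.5), function(sp) {
    spec <- phantom_spec(axes_mm = c(10, 10, 10),
                         center_mm = c(30.3, 0.2, 0.1), cysts = list(),
                         spacing_mm = c(sp, sp, sp),
                         in_plane_size = if (sp < 1) 128L else 64L,
                         n_frames = if (sp < 1) 96L else 48L,
                         n_blank_edge = 2L,
                         sector_fov = list(apex_mm = -15, width_deg = 70,
                                           depth_mm = 100),
                         speckle_scale = 0, seed = 1)
    r <- render_phantom(spec)
    abs(mask_volume(r$mask) - r$analytic_volume_mL) / r$analytic_volume_mL
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
})

test_that("interior cysts darken the image but not the mask", {
  base <- phantom_spec(axes_mm = c(30, 22, 20), center_mm = c(80, 0, 0),
                       cysts = list(), in_plane_size = 64L, n_frames = 24L,
                       spacing_mm = c(3, 3, 4), speckle_scale = 0, seed = 5)
  withc <- base
  withc$cysts <- list(list(center = c(5, 3, 0), radius = 6))
  r0 <- render_phantom(base)
  r1 <- render_phantom(withc)
  expect_identical(r0$mask$voxels, r1$mask$voxels)
  expect_equal(r1$analytic_volume_mL, r0$analytic_volume_mL)
  expect_lt(mean(r1$stack$voxels[r1$mask$voxels == 1]),
            mean(r0$stack$voxels[r0$mask$voxels == 1]))
})

test_that("noise-free full-gain render keeps the capsule rim brighter than the interior", {
  spec <- phantom_spec(axes_mm = c(30, 22, 20), center_mm = c(80, 0, 0),
                       cysts = list(), in_plane_size = 64L, n_frames = 24L,
                       spacing_mm = c(3, 3, 4), speckle_scale = 0,
                       gain = 0.68, seed = 2)
  r <- render_phantom(spec)
  grid <- sonotkv:::phantom_grid(spec)
  q <- sonotkv:::ellipsoid_form(spec, grid)
  fov <- array(FALSE, dim(q))
  sec <- sonotkv:::sector_geometry(spec, grid)
  fov[, , sonotkv:::recorded_frames(spec)] <- sec$inside
  rim <- q >= 0.85 & q <= 1.0 & fov
  interior <- q < 0.6 & fov
  expect_gt(mean(r$stack$voxels[rim]), mean(r$stack$voxels[interior]))
})

test_that("scan triples reproduce and stay volumetrically consistent", {
  spec <- sample_spec(3, "centered", in_plane_size = 64L, n_frames = 24L,
                      spacing_mm = c(3, 3, 4))
  tr <- render_scan_triple(spec, 11)
  tr2 <- render_scan_triple(spec, 11)
  expect_identical(tr[[2]]$stack$voxels, tr2[[2]]$stack$voxels)
  v <- vapply(tr, function(t) mask_volume(t$mask), numeric(1))
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(abs(v[i] - v[j]) / mean(v[c(i, j)]), 0.10)
  expect_identical(vapply(tr, function(t) t$stack$scan_index, integer(1)),
                   1:3)
  tr0 <- render_scan_triple(spec, 11, jitter = 0)
  expect_identical(tr0[[1]]$stack$voxels, tr0[[2]]$stack$voxels)
  expect_identical(tr0[[1]]$stack$voxels, tr0[[3]]$stack$voxels)
})

test_that("stacks and masks round-trip through NIfTI", {
  r <- tiny_phantom()
  tf <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(r$stack, tf)
  back <- read_nifti_volume(tf, "stack", patient_id = "p", side = "left")
  expect_equal(back$voxels, r$stack$voxels, ignore_attr = TRUE)
  expect_equal(back$spacing, r$stack$spacing, tolerance = 1e-6)
  tm <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(r$mask, tm)
  mback <- read_nifti_volume(tm, "mask")
  expect_identical(mback$voxels, r$mask$voxels)
  unlink(c(tf, tm))
})
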