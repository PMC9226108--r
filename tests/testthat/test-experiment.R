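test_that("patient-level splits are disjoint, deterministic and sized", {
  ids <- sprintf("PKD_%03d", 1:22)
  sp <- split_cohort(ids, c(15, 2, 5), seed = 3)
  expect_length(sp$train, 15)
  expect_length(sp$val, 2)
  expect_length(sp$test, 5)
  expect_length(intersect(sp$train, c(sp$val, sp$test)), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  expect_identical(sp, split_cohort(ids, c(15, 2, 5), seed = 3))
  expect_false(identical(sp, split_cohort(ids, c(15, 2, 5), seed = 4)))
  # 6 scans per patient: the clinical design arithmetic
  expect_equal(6 * lengths(sp[c("train", "val", "test")]),
               c(train = 90, val = 12, test = 30))
  all_train <- split_cohort(ids, c(22, 0, 0), seed = 1)
  expect_length(all_train$train, 22)
  expect_length(all_train$test, 0)
  expect_error(split_cohort(ids[1:4], c(15, 2, 5)), "exceeds")
})

test_that("fleet simulation yields complete scan triples with demographics", {
  cfg <- experiment_config(n_patients = 2L, split = c(1L, 0L, 1L),
                           in_plane_size = 64L, n_frames = 24L,
                           spacing_mm = c(3, 3, 4), seed = 5)
  fleet <- simulate_fleet(cfg)
  expect_length(fleet$scans, 2 * 2 * 3)
  expect_equal(nrow(fleet$demographics), 2)
  key <- vapply(fleet$scans, function(s)
    paste(s$patient_id, s$side, s$scan_index), character(1))
  expect_false(anyDuplicated(key) > 0)
  vols <- vapply(fleet$scans, function(s) mask_volume(s$mask), numeric(1))
  expect_true(all(vols > 10))
  expect_true(all(fleet$demographics$age >= 28 &
                    fleet$demographics$age <= 75))
})

test_that("a smoke-scale experiment runs end to end and serializes", {
  cfg <- experiment_config(n_patients = 3L, split = c(2L, 0L, 1L),
                           in_plane_size = 64L, n_frames = 24L,
                           spacing_mm = c(3, 3, 4), seed = 7,
                           preprocess = preprocess_config(64L, 32L),
                           augment = augment_config(multiplier = 1L),
                           unet = unet_config(levels = 4L, base_filters = 4L,
                                              slab_size = 32L,
                                              learning_rate = 1e-3,
                                              epochs = 2L, batch_size = 8L),
                           slab_stride = 6L)
  out <- tempfile("exp")
  rep <- run_phantom_experiment(cfg, out_dir = out)
  expect_s3_class(rep, "experiment_report")
  expect_equal(nrow(rep$volumes), 6)        # 1 test patient x 6 scans
  expect_length(rep$metrics, 6)
  expect_equal(nrow(rep$curves), 2)
  expect_equal(ncol(rep$decile_profiles), 10)
  expect_true(is.finite(rep$interscan_mL))
  expect_true(all(c("volumes.csv", "metrics.csv", "curves.csv",
                    "decile_dsc.csv", "report.json") %in% list.files(out)))
  expect_true(all(rep$classification$counts >= 0))
  # classification covers the test patients for both sources (ai, truth)
  expect_equal(unname(rowSums(rep$classification$counts)), c(1, 1))
  unlink(out, recursive = TRUE)
})

test_that("experiment reports are reproducible under a fixed seed", {
  cfg <- experiment_config(n_patients = 2L, split = c(1L, 0L, 1L),
                           in_plane_size = 64L, n_frames = 24L,
                           spacing_mm = c(3, 3, 4), seed = 11,
                           preprocess = preprocess_config(64L, 32L),
                           augment = augment_config(multiplier = 1L),
                           unet = unet_config(levels = 3L, base_filters = 2L,
                                              slab_size = 32L,
                                              learning_rate = 1e-3,
                                              epochs = 1L, batch_size = 8L),
                           slab_stride = 8L)
  r1 <- run_phantom_experiment(cfg)
  r2 <- run_phantom_experiment(cfg)
  expect_equal(r1$volumes, r2$volumes, tolerance = 1e-12)
  expect_equal(r1$curves, r2$curves, tolerance = 1e-12)
})
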