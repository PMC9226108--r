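test_that("confusion counts enumerate the toy grid correctly", {
  pred <- matrix(c(1, 0, 1, 0), 2, 2)   # rows (1,1 / 0,0) column-major
  ref <- matrix(c(1, 1, 0, 0), 2, 2)    # rows (1,0 / 1,0)
  cc <- confusion_counts(array(pred, c(2, 2, 1)), array(ref, c(2, 2, 1)))
  expect_equal(unname(cc), c(1, 1, 1, 1))
  expect_equal(sum(cc), 4)
  a <- random_mask_array(c(4, 4, 2))
  expect_equal(unname(confusion_counts(a, a)[c("fp", "fn")]), c(0, 0))
  expect_equal(unname(confusion_counts(1 - a, a)[c("tp", "tn")]), c(0, 0))
  expect_error(confusion_counts(array(0, c(2, 2, 2)), array(0, c(2, 2, 3))),
               "differ")
})

test_that("overlap metrics reproduce hand-derived values and conventions", {
  om <- overlap_metrics(c(tp = 2, fp = 2, fn = 2, tn = 2))
  expect_equal(om$mcc, 0)
  # printed-pair consistency: DSC 0.80 pairs with Jaccard 2/3
  expect_equal(0.80 / (2 - 0.80), 2 / 3, tolerance = 1e-12)
  om2 <- overlap_metrics(c(tp = 8, fp = 1, fn = 3, tn = 20))
  expect_equal(om2$jaccard, om2$dsc / (2 - om2$dsc), tolerance = 1e-12)
  idm <- overlap_metrics(c(tp = 5, fp = 0, fn = 0, tn = 11))
  expect_equal(idm$dsc, 1); expect_equal(idm$jaccard, 1)
  expect_equal(idm$vs, 1); expect_equal(idm$fn_rate, 0)
  # degenerate conventions are flagged, not silently zeroed
  both_empty <- overlap_metrics(c(tp = 0, fp = 0, fn = 0, tn = 9))
  expect_equal(both_empty$dsc, 1)
  expect_true("dsc" %in% attr(both_empty, "undefined"))
  expect_true(is.na(both_empty$fn_rate))
  expect_error(overlap_metrics(c(tp = 0, fp = 0, fn = 0, tn = 0)), "zero")
})

test_that("every panel metric matches its brute-force oracle on random masks", {
  set.seed(31)
  for (i in 1:40) {
    mp <- random_mask_pair(c(8, 8, 8))
    om <- overlap_metrics(confusion_counts(mp$pred, mp$ref))
    oc <- oracle_overlap(mp$pred, mp$ref)
    for (nm in c("dsc", "jaccard", "fn_rate", "mcc", "vs"))
      expect_equal(om[[nm]], oc[[nm]], tolerance = 1e-9, label = nm)
    expect_gte(om$vs, om$dsc)
    expect_equal(om$jaccard, om$dsc / (2 - om$dsc), tolerance = 1e-12)
    h <- hd95(mp$pred, mp$ref)
    expect_equal(h, oracle_hd95(mp$pred, mp$ref), tolerance = 1e-9)
    prob <- array(runif(length(mp$pred)), dim(mp$pred))
    expect_equal(roc_auc(prob, mp$ref), oracle_auc(prob, mp$ref),
                 tolerance = 1e-9)
  }
})

test_that("mcc is invariant under simultaneous label swap", {
  set.seed(5)
  mp <- random_mask_pair()
  m1 <- overlap_metrics(confusion_counts(mp$pred, mp$ref))$mcc
  m2 <- overlap_metrics(confusion_counts(1 - mp$pred, 1 - mp$ref))$mcc
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("hd95 handles worked geometries, symmetry and spacing", {
  a <- array(0L, c(12, 12, 3)); a[4, 4, 2] <- 1L
  b <- array(0L, c(12, 12, 3)); b[4, 9, 2] <- 1L
  expect_equal(hd95(a, b), 5.0)
  expect_equal(hd95(a, a), 0)
  set.seed(9)
  mp <- random_mask_pair(c(16, 16, 16))
  expect_equal(hd95(mp$pred, mp$ref), hd95(mp$ref, mp$pred))
  ma <- make_mask(a, c(2, 2, 2)); mb <- make_mask(b, c(2, 2, 2))
  expect_equal(hd95(ma, mb, use_spacing = TRUE), 10.0)
  empty <- array(0L, c(12, 12, 3))
  expect_warning(h <- hd95(a, empty), "empty")
  expect_true(is.na(h))
})

test_that("roc auc follows the rank statistic with tie averaging", {
  ref <- array(c(1, 1, 1, 0, 0, 0), c(6, 1, 1))
  prob <- array(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.1), c(6, 1, 1))
  expect_equal(roc_auc(prob, ref), 8 / 9, tolerance = 1e-12)
  expect_equal(roc_auc(array(ref, c(6, 1, 1)), ref), 1.0)
  expect_equal(roc_auc(array(0.4, c(6, 1, 1)), ref), 0.5)
  allpos <- array(1, c(6, 1, 1))
  expect_warning(a <- roc_auc(prob, allpos), "single-class")
  expect_true(is.na(a))
})

test_that("slice-decile profile partitions the kidney extent", {
  dims <- c(16, 16, 24)
  ref <- array(0L, dims)
  ref[5:12, 5:12, 3:22] <- 1L      # 20-frame extent -> 2 frames per bin
  rm <- make_mask(ref)
  prof <- slice_decile_dsc(rm, rm)
  expect_equal(prof$dsc_by_decile, rep(1, 10))
  expect_equal(unname(prof$slice_extent), c(3, 22))
  bins <- floor(10 * (3:22 - 3) / 20) + 1
  expect_true(all(table(bins) == 2))
  pred <- ref
  pred[, , 3:4] <- 0L              # first decile emptied
  p2 <- slice_decile_dsc(make_mask(pred), rm)
  expect_equal(p2$dsc_by_decile, c(0, rep(1, 9)))
  expect_error(slice_decile_dsc(rm, make_mask(array(0L, dims))), "empty")
})

test_that("metric_report assembles the panel consistently", {
  set.seed(20)
  mp <- random_mask_pair(c(10, 10, 6))
  prob <- array(runif(600), c(10, 10, 6))
  rep <- metric_report(make_mask(mp$pred), make_mask(mp$ref), prob = prob)
  om <- overlap_metrics(confusion_counts(mp$pred, mp$ref))
  expect_equal(rep$dsc, om$dsc)
  expect_equal(rep$auc, oracle_auc(prob, mp$ref), tolerance = 1e-9)
  expect_equal(rep$tp + rep$fp + rep$fn + rep$tn, 600)
  summ <- summarize_metric_reports(list(rep, rep))
  expect_equal(nrow(summ), 4)  # 2 scans + mean + sd rows
  expect_equal(summ$dsc[3], rep$dsc)
  expect_equal(summ$dsc[4], 0)
})
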