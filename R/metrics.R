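#' Voxelwise confusion counts
#'
#' @param pred,ref aligned binary volumes ([seg_mask()] or plain arrays).
#' @return named numeric vector (tp, fp, fn, tn); the four counts sum to the
#'   total voxel count.
#' @export
confusion_counts <- function(pred, ref) {
  p <- if (inherits(pred, "seg_mask")) pred$voxels else pred
  r <- if (inherits(ref, "seg_mask")) ref$voxels else ref
  if (!identical(dim(p), dim(r))) stopf("pred and ref shapes differ")
  assert_binary(p, "pred"); assert_binary(r, "ref")
  # doubles, not integers: products like tp * tn overflow 32-bit counts
  tp <- as.numeric(sum(p == 1 & r == 1))
  fp <- as.numeric(sum(p == 1 & r == 0))
  fn <- as.numeric(sum(p == 0 & r == 1))
  tn <- as.numeric(sum(p == 0 & r == 0))
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Overlap metrics from confusion counts
#'
#' Computes the overlap panel: Dice similarity coefficient
#' `2tp / (2tp + fp + fn)`, Jaccard index `tp / (tp + fp + fn)`,
#' false-negative rate `fn / (tp + fn)` (i.e. 1 - sensitivity), Matthews
#' correlation coefficient, and volume similarity
#' `1 - |fn - fp| / (2tp + fp + fn)`.
#'
#' Degenerate-input conventions, flagged in the `undefined` attribute rather
#' than silently zeroed: two empty masks give dsc = jaccard = vs = 1;
#' `fn_rate` is `NA` when the reference is empty (tp + fn = 0); `mcc` is
#' `NA` when any marginal is empty.
#'
#' @param counts vector from [confusion_counts()], or `tp` as a scalar.
#' @param fp,fn,tn scalars when `counts` is given piecewise.
#' @return named list (dsc, jaccard, fn_rate, mcc, vs) with attribute
#'   `undefined` naming flagged entries.
#' @export
overlap_metrics <- function(counts, fp = NULL, fn = NULL, tn = NULL) {
  if (!is.null(fp)) counts <- c(tp = counts, fp = fp, fn = fn, tn = tn)
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  if (any(c(tp, fp, fn, tn) < 0)) stopf("counts must be non-negative")
  undef <- character(0)
  if (tp + fp + fn + tn == 0) stopf("all confusion counts are zero")
  if (tp + fp + fn == 0) {
    dsc <- 1; jac <- 1; vs <- 1
    undef <- c(undef, "dsc", "jaccard", "vs")
  } else {
    dsc <- 2 * tp / (2 * tp + fp + fn)
    jac <- tp / (tp + fp + fn)
    vs <- 1 - abs(fn - fp) / (2 * tp + fp + fn)
  }
  fn_rate <- if (tp + fn == 0) { undef <- c(undef, "fn_rate"); NA_real_
  } else fn / (tp + fn)
  mden <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mden == 0) { undef <- c(undef, "mcc"); NA_real_
  } else (tp * tn - fp * fn) / mden
  structure(list(dsc = dsc, jaccard = jac, fn_rate = fn_rate, mcc = mcc,
                 vs = vs),
            undefined = undef)
}

#' 95th-percentile surface distance (HD-95)
#'
#' Pools the symmetric surface-distance distribution -- from every boundary
#' voxel of each mask to the nearest boundary voxel of the other -- and
#' returns its 95th percentile.  Boundary voxels are foreground voxels with a
#' background 6-neighbour (or on the array edge).  Units are voxels unless
#' `use_spacing` converts to mm.  The directed-average variant (mean of the
#' two directed 95th percentiles) is available via `variant`.
#'
#' @param pred,ref non-empty aligned binary masks.
#' @param use_spacing use the mask spacing (mm) instead of voxel units.
#' @param variant `"pooled"` (default) or `"directed_average"`.
#' @param percentile distance percentile (default 0.95).
#' @return distance; `NA` with a warning when either mask is empty.
#' @export
hd95 <- function(pred, ref, use_spacing = FALSE,
                 variant = c("pooled", "directed_average"),
                 percentile = 0.95) {
  variant <- match.arg(variant)
  p <- if (inherits(pred, "seg_mask")) pred$voxels else pred
  r <- if (inherits(ref, "seg_mask")) ref$voxels else ref
  if (!identical(dim(p), dim(r))) stopf("pred and ref shapes differ")
  if (sum(p) == 0 || sum(r) == 0) {
    warning("hd95 undefined for an empty mask", call. = FALSE)
    return(NA_real_)
  }
  sp <- if (use_spacing) {
    if (inherits(pred, "seg_mask")) pred$spacing else stopf(
      "use_spacing requires seg_mask inputs carrying spacing")
  } else c(1, 1, 1)
  storage.mode(p) <- "integer"; storage.mode(r) <- "integer"
  bp <- cpp_boundary_voxels(p)
  br <- cpp_boundary_voxels(r)
  d_pr <- cpp_min_distances(bp, br, sp)
  d_rp <- cpp_min_distances(br, bp, sp)
  if (variant == "pooled")
    stats::quantile(c(d_pr, d_rp), percentile, names = FALSE)
  else
    mean(c(stats::quantile(d_pr, percentile, names = FALSE),
           stats::quantile(d_rp, percentile, names = FALSE)))
}

#' Voxelwise ROC AUC
#'
#' Area under the ROC curve of predicted probabilities against reference
#' labels, computed as the rank (Mann-Whitney) statistic with ties averaged.
#'
#' @param prob numeric probability volume.
#' @param ref aligned binary reference.
#' @return AUC in [0, 1]; `NA` with a warning when the reference has a
#'   single class.
#' @export
roc_auc <- function(prob, ref) {
  r <- if (inherits(ref, "seg_mask")) ref$voxels else ref
  if (!identical(dim(prob), dim(r))) stopf("prob and ref shapes differ")
  y <- as.vector(r); s <- as.vector(prob)
  # doubles: n1 * n0 overflows integer arithmetic on volume-sized inputs
  n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) {
    warning("roc_auc undefined for a single-class reference", call. = FALSE)
    return(NA_real_)
  }
  rk <- rank(s)
  (sum(rk[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full segmentation metric report
#'
#' The seven-metric evaluation panel for one scan: DSC, Jaccard, FN rate,
#' MCC, HD-95, volume similarity and (when a probability volume is supplied)
#' ROC AUC, plus the raw confusion counts.  Because background dominates a
#' full sweep, the TN-dependent metrics (MCC, AUC) are computed over the
#' informative-frame domain only when `frames` is given.
#'
#' @param pred predicted [seg_mask()].
#' @param ref reference [seg_mask()].
#' @param prob optional probability volume aligned with `pred`.
#' @param frames optional frame indices restricting the evaluation domain.
#' @param use_spacing report HD-95 in mm instead of voxels.
#' @return list of class `metric_report`.
#' @export
metric_report <- function(pred, ref, prob = NULL, frames = NULL,
                          use_spacing = FALSE) {
  check_aligned(pred, ref)
  sub <- function(v) if (is.null(frames)) v else v[, , frames, drop = FALSE]
  pv <- sub(pred$voxels); rv <- sub(ref$voxels)
  cc <- confusion_counts(pv, rv)
  om <- overlap_metrics(cc)
  h <- hd95(seg_mask(pv, pred$spacing), seg_mask(rv, ref$spacing),
            use_spacing = use_spacing)
  auc <- if (!is.null(prob)) roc_auc(sub(prob), rv) else NA_real_
  structure(c(om, list(hd95 = h, auc = auc,
                       tp = cc[["tp"]], fp = cc[["fp"]],
                       fn = cc[["fn"]], tn = cc[["tn"]])),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("DSC %.3f  Jaccard %.3f  FN %.3f  MCC %.3f  ",
                     "HD95 %.2f  VS %.3f  AUC %s\n"),
              x$dsc, x$jaccard, x$fn_rate, x$mcc, x$hd95, x$vs,
              ifelse(is.na(x$auc), "-", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Summarize metric reports as mean and SD rows
#'
#' @param reports list of `metric_report`s (one per scan).
#' @return data.frame with one row per scan plus `mean` and `sd` rows.
#' @export
summarize_metric_reports <- function(reports) {
  cols <- c("dsc", "jaccard", "fn_rate", "mcc", "hd95", "vs", "auc")
  m <- do.call(rbind, lapply(reports, function(r)
    unlist(r[cols], use.names = TRUE)))
  df <- as.data.frame(m)
  rbind(cbind(scan = seq_len(nrow(df)), df),
        cbind(scan = NA, as.data.frame(t(colMeans(df, na.rm = TRUE)))),
        cbind(scan = NA, as.data.frame(t(apply(df, 2, stats::sd,
                                               na.rm = TRUE)))))
}

#' Slice-decile Dice profile
#'
#' The sweep extent containing the reference kidney (first through last
#' frame with foreground) is split into 10 contiguous bins; frame `i` (with
#' `i` counted from the extent start) falls into bin
#' `floor(10 * i / extent_length) + 1`.  Within each bin, Dice is pooled
#' over the bin's frames (`2*sum(tp) / (2*sum(tp) + sum(fp) + sum(fn))`).
#' Bins where both reference and prediction are empty are `NA`.  The
#' frame-averaged variant (mean of per-frame Dice) is available via
#' `pooling`.
#'
#' @param pred,ref aligned binary masks; `ref` must be non-empty.
#' @param pooling `"pooled"` (default) or `"frame_average"`.
#' @return list with `dsc_by_decile` (length 10) and `slice_extent`
#'   (z_start, z_end).
#' @export
slice_decile_dsc <- function(pred, ref, pooling = c("pooled",
                                                    "frame_average")) {
  pooling <- match.arg(pooling)
  check_aligned(pred, ref)
  per_frame_fg <- apply(ref$voxels, 3, sum)
  if (sum(per_frame_fg) == 0) stopf("reference mask is empty")
  z0 <- min(which(per_frame_fg > 0)); z1 <- max(which(per_frame_fg > 0))
  len <- z1 - z0 + 1L
  bins <- pmin(floor(10 * (seq.int(z0, z1) - z0) / len) + 1L, 10L)
  dsc <- rep(NA_real_, 10)
  for (b in 1:10) {
    zz <- seq.int(z0, z1)[bins == b]
    if (length(zz) == 0L) next
    pv <- pred$voxels[, , zz, drop = FALSE]
    rv <- ref$voxels[, , zz, drop = FALSE]
    if (pooling == "pooled") {
      tp <- sum(pv == 1 & rv == 1)
      fp <- sum(pv == 1 & rv == 0)
      fn <- sum(pv == 0 & rv == 1)
      if (2 * tp + fp + fn > 0) dsc[b] <- 2 * tp / (2 * tp + fp + fn)
    } else {
      vals <- vapply(seq_along(zz), function(j) {
        tp <- sum(pv[, , j] == 1 & rv[, , j] == 1)
        fp <- sum(pv[, , j] == 1 & rv[, , j] == 0)
        fn <- sum(pv[, , j] == 0 & rv[, , j] == 1)
        if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
      }, numeric(1))
      if (!all(is.na(vals))) dsc[b] <- mean(vals, na.rm = TRUE)
    }
  }
  list(dsc_by_decile = dsc, slice_extent = c(z_start = z0, z_end = z1))
}
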