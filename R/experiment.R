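#' Patient-level dataset split
#'
#' Random, seeded partition of patients into train/validation/test sets.
#' Because every patient contributes 6 scans (2 kidneys x 3 sweeps), a
#' (15, 2, 5) split of 22 patients yields 90/12/30 scans.  The split is at
#' the patient level so no patient's scans cross partitions.
#'
#' @param patient_ids character vector of unique patient identifiers.
#' @param ratio integer triple (train, val, test); must sum to at most the
#'   cohort size.
#' @param seed RNG seed.
#' @return list with `train`, `val`, `test` patient vectors.
#' @export
split_cohort <- function(patient_ids, ratio = c(15L, 2L, 5L), seed = 1L) {
  patient_ids <- unique(as.character(patient_ids))
  if (length(ratio) != 3L || any(ratio < 0))
    stopf("ratio must be three non-negative counts")
  if (sum(ratio) > length(patient_ids))
    stopf("split ratio %s exceeds the %d available patients",
          paste(ratio, collapse = ":"), length(patient_ids))
  with_seed(child_seed(seed, "split"), {
    perm <- sample(patient_ids)
    list(train = sort(perm[seq_len(ratio[1])]),
         val = sort(perm[ratio[1] + seq_len(ratio[2])]),
         test = sort(perm[ratio[1] + ratio[2] + seq_len(ratio[3])]))
  })
}

#' Experiment configuration for the phantom study
#'
#' Bundles every stage configuration of the desk-scale end-to-end
#' experiment: phantom fleet size and geometry, the patient-level split,
#' preprocessing, augmentation and network training settings.  The defaults
#' are the desk-scale study conditions: 12 phantom patients (8/1/3 split),
#' 128 x 128 x 48 stacks, a mixed bag of acquisition difficulties, 64 px
#' model slabs and a narrow (base 8 filters) six-level U-Net trained from
#' random initialization at a desk-appropriate learning rate.
#'
#' @param n_patients number of phantom patients.
#' @param split patient-level (train, val, test) counts.
#' @param difficulty_mix difficulties cycled across kidneys.
#' @param in_plane_size,n_frames,spacing_mm phantom stack geometry.
#' @param seed master seed; all stage seeds derive from it.
#' @param preprocess a [preprocess_config()].
#' @param augment an [augment_config()].
#' @param unet a [unet_config()].
#' @param epochs,learning_rate training overrides.
#' @param slab_stride take every `slab_stride`-th informative frame as a
#'   training slab (all frames are always used at prediction time).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_patients = 12L, split = c(8L, 1L, 3L),
                              difficulty_mix = c("centered", "small_fov",
                                                 "low_contrast", "centered"),
                              in_plane_size = 128L, n_frames = 48L,
                              spacing_mm = c(1.5, 1.5, 2.0), seed = 1L,
                              preprocess = preprocess_config(
                                target_inplane = 128L, slab_size = 64L),
                              augment = augment_config(multiplier = 2L),
                              unet = unet_config(levels = 6L,
                                                 base_filters = 8L,
                                                 slab_size = 64L,
                                                 learning_rate = 1e-3,
                                                 epochs = 8L,
                                                 batch_size = 8L),
                              epochs = NULL, learning_rate = NULL,
                              slab_stride = 4L) {
  structure(list(n_patients = as.integer(n_patients),
                 split = as.integer(split),
                 difficulty_mix = difficulty_mix,
                 in_plane_size = as.integer(in_plane_size),
                 n_frames = as.integer(n_frames),
                 spacing_mm = spacing_mm, seed = as.integer(seed),
                 preprocess = preprocess, augment = augment, unet = unet,
                 epochs = epochs, learning_rate = learning_rate,
                 slab_stride = as.integer(slab_stride)),
            class = "experiment_config")
}

#' Simulate a phantom patient fleet
#'
#' Each phantom patient gets two kidneys (left/right), each drawn from the
#' difficulty mix and rendered as a scan triple, plus synthetic demographics
#' (age, height) for downstream severity classification.
#'
#' @param cfg an [experiment_config()].
#' @return list with `scans` (list of
#'   `list(stack, mask, analytic_volume_mL, patient_id, side, scan_index)`)
#'   and `demographics` (data.frame patient_id, age, height_m).
#' @export
simulate_fleet <- function(cfg = experiment_config()) {
  scans <- list()
  demo <- list()
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("PH%03d", p)
    dg <- with_seed(child_seed(cfg$seed, "demo", p),
                    data.frame(patient_id = pid,
                               age = round(stats::runif(1, 28, 75)),
                               height_m = round(stats::runif(1, 1.55, 1.92),
                                                2)))
    demo[[p]] <- dg
    for (side in c("left", "right")) {
      diff <- cfg$difficulty_mix[
        ((p - 1) * 2 + (side == "right")) %% length(cfg$difficulty_mix) + 1]
      spec <- sample_spec(child_seed(cfg$seed, "kidney", p, side), diff,
                          in_plane_size = cfg$in_plane_size,
                          n_frames = cfg$n_frames,
                          spacing_mm = cfg$spacing_mm)
      triple <- render_scan_triple(spec,
                                   child_seed(cfg$seed, "jitter", p, side),
                                   patient_id = pid, side = side)
      for (r in triple) {
        scans[[length(scans) + 1L]] <-
          list(stack = r$stack, mask = r$mask,
               analytic_volume_mL = r$analytic_volume_mL,
               patient_id = pid, side = side,
               scan_index = r$stack$scan_index)
      }
    }
  }
  list(scans = scans, demographics = do.call(rbind, demo))
}

# Training slabs for one scan: every slab_stride-th informative frame, with
# augmented variants appended.
scan_to_slabs <- function(scan, cfg, augmented = TRUE) {
  std <- standardize_stack(scan$stack, cfg$preprocess, scan$mask)
  kept <- filter_blank_frames(std$stack, cfg$preprocess)
  if (length(kept) == 0L) return(list())
  take <- kept[seq(1, length(kept), by = cfg$slab_stride)]
  out <- list()
  for (i in seq_along(take)) {
    sl <- make_slab(std$stack, take[i], cfg$preprocess, std$mask)
    pairs <- if (augmented) {
      acfg <- cfg$augment
      acfg$seed <- child_seed(cfg$seed, "aug", scan$patient_id, scan$side,
                              scan$scan_index)
      augment_pair(sl$image, sl$mask, acfg, index = i)
    } else list(list(image = sl$image, mask = sl$mask))
    for (pr in pairs)
      out[[length(out) + 1L]] <- list(x = pr$image / 255, y = pr$mask,
                                      patient_id = scan$patient_id)
  }
  out
}

#' Run the end-to-end phantom experiment
#'
#' Simulate -> preprocess -> augment -> train -> predict -> volumetry ->
#' metrics -> agreement -> classification, all seeded from the experiment
#' config.  This is the desk-scale analogue of the full clinical study; the
#' returned report carries every downstream table.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional directory for serialized artifacts (volume and
#'   metric CSVs, training-curve CSV, report JSON).
#' @param verbose print stage progress.
#' @return list of class `experiment_report`: `split`, `curves`,
#'   `metrics` (per-test-scan [metric_report()]s), `metric_summary`,
#'   `volumes` (per-scan predicted vs reference), `agreement`
#'   (predicted-vs-truth R2 and Bland-Altman), `interscan_mL`,
#'   `decile_profiles`, `classification`, `demographics`.
#' @export
run_phantom_experiment <- function(cfg = experiment_config(),
                                   out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("[simulate] %d phantom patients", cfg$n_patients)
  fleet <- simulate_fleet(cfg)
  split <- split_cohort(fleet$demographics$patient_id, cfg$split, cfg$seed)

  say("[preprocess] building training slabs")
  part_of <- function(pid)
    if (pid %in% split$train) "train"
    else if (pid %in% split$val) "val" else "test"
  train_slabs <- list(); val_slabs <- list()
  for (scan in fleet$scans) {
    part <- part_of(scan$patient_id)
    if (part == "test") next
    slabs <- scan_to_slabs(scan, cfg, augmented = (part == "train"))
    if (part == "train") train_slabs <- c(train_slabs, slabs)
    else val_slabs <- c(val_slabs, slabs)
  }
  say("[train] %d train / %d val slabs", length(train_slabs),
      length(val_slabs))
  ucfg <- cfg$unet
  ucfg$seed <- child_seed(cfg$seed, "unet")
  model <- build_unet(ucfg)
  model <- train_unet(model, train_slabs, val_slabs,
                      epochs = cfg$epochs, learning_rate = cfg$learning_rate,
                      verbose = verbose)

  say("[predict] evaluating test scans")
  test_scans <- Filter(function(s) part_of(s$patient_id) == "test",
                       fleet$scans)
  reports <- list(); profiles <- list()
  vol_rows <- list()
  for (scan in test_scans) {
    std <- standardize_stack(scan$stack, cfg$preprocess, scan$mask)
    pr <- predict_stack(model, std$stack, cfg$preprocess)
    rep <- metric_report(pr$mask, std$mask, prob = pr$prob,
                         frames = if (length(pr$kept) > 0) pr$kept else NULL)
    reports[[length(reports) + 1L]] <- rep
    profiles[[length(profiles) + 1L]] <-
      slice_decile_dsc(pr$mask, std$mask)$dsc_by_decile
    vol_rows[[length(vol_rows) + 1L]] <-
      data.frame(patient_id = scan$patient_id, side = scan$side,
                 scan_index = scan$scan_index,
                 predicted_mL = mask_volume(pr$mask),
                 reference_mL = mask_volume(std$mask),
                 analytic_mL = scan$analytic_volume_mL)
  }
  vols <- do.call(rbind, vol_rows)

  say("[stats] agreement, variability, classification")
  agree <- compare_methods(vols$predicted_mL, vols$reference_mL)
  rec_pred <- volume_records(vols$patient_id, vols$side, vols$scan_index,
                             vols$predicted_mL, "ai")
  rec_ref <- volume_records(vols$patient_id, vols$side, vols$scan_index,
                            vols$reference_mL, "truth")
  interscan <- interscan_variability(rec_pred)
  tkv <- rbind(patient_tkv_table(rec_pred), patient_tkv_table(rec_ref))
  names(tkv)[names(tkv) == "tkv_mL"] <- "tkv_mL"
  cls <- classify_cohort(tkv, fleet$demographics)

  report <- structure(
    list(split = split, curves = model$curves, metrics = reports,
         metric_summary = summarize_metric_reports(reports),
         volumes = vols, agreement = agree, interscan_mL = interscan,
         decile_profiles = do.call(rbind, profiles),
         classification = cls, demographics = fleet$demographics,
         model = model, config = cfg),
    class = "experiment_report")
  if (!is.null(out_dir)) write_experiment_report(report, out_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  md <- mean(vapply(x$metrics, function(r) r$dsc, numeric(1)))
  cat(sprintf("Phantom experiment: %d test scans, mean DSC %.3f\n",
              nrow(x$volumes), md))
  cat(sprintf("  volume agreement: R2 %.3f, bias %.2f%%\n",
              x$agreement$r2, x$agreement$bland_altman$bias_pct))
  cat(sprintf("  interscan variability %.2f mL\n", x$interscan_mL))
  invisible(x)
}

#' Serialize an experiment report
#'
#' Writes volume and metric tables as CSV, training curves as CSV, and a
#' JSON summary under `out_dir`.
#'
#' @param report an `experiment_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_experiment_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$volumes, file.path(out_dir, "volumes.csv"),
                   row.names = FALSE)
  utils::write.csv(report$metric_summary,
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(report$curves, file.path(out_dir, "curves.csv"),
                   row.names = FALSE)
  dec <- as.data.frame(report$decile_profiles)
  names(dec) <- sprintf("decile_%02d", 1:10)
  utils::write.csv(dec, file.path(out_dir, "decile_dsc.csv"),
                   row.names = FALSE)
  summ <- list(mean_test_dsc = mean(vapply(report$metrics,
                                           function(r) r$dsc, numeric(1))),
               volume_r2 = report$agreement$r2,
               ba_bias_pct = report$agreement$bland_altman$bias_pct,
               interscan_mL = report$interscan_mL,
               split = report$split)
  jsonlite::write_json(summ, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
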