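#' Kidney volume of a binary mask
#'
#' Foreground voxel count times the voxel volume, in millilitres:
#' `n_fg * dx * dy * dz / 1000`.
#'
#' @param mask a [seg_mask()].
#' @return volume in mL.
#' @export
mask_volume <- function(mask) {
  assert_binary(mask$voxels)
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

#' Build a kidney-volume record table
#'
#' Canonical long-format table of per-scan kidney volumes; one row per
#' (patient, side, scan, source).
#'
#' @param patient_id,side,scan_index,volume_mL,source vectors of equal
#'   length; `source` is one of `"reader1"`, `"reader2"`, `"ai"`, `"mri"`,
#'   `"truth"`.
#' @return data.frame of class `volume_records`.
#' @export
volume_records <- function(patient_id, side, scan_index, volume_mL,
                           source = "ai") {
  df <- data.frame(patient_id = as.character(patient_id),
                   side = as.character(side),
                   scan_index = as.integer(scan_index),
                   volume_mL = as.numeric(volume_mL),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  if (any(df$volume_mL < 0)) stopf("volumes must be non-negative")
  if (!all(df$side %in% c("left", "right"))) stopf("side must be left/right")
  key <- with(df, paste(patient_id, side, scan_index, source))
  if (anyDuplicated(key))
    stopf("duplicate (patient, side, scan, source) records")
  class(df) <- c("volume_records", "data.frame")
  df
}

#' Patient-level total kidney volume
#'
#' For each scan index, left and right kidney volumes are added to a
#' per-observation TKV; the patient TKV is the mean over observations.  A
#' scan index with only one side present is rejected by name.
#'
#' @param records a [volume_records()] table for one patient and one source.
#' @return list with `patient_id`, `source`, `tkv_mL`, `n_observations`,
#'   and the per-observation TKVs `per_scan_mL`.
#' @export
patient_tkv <- function(records) {
  if (length(unique(records$patient_id)) != 1L)
    stopf("patient_tkv expects records of a single patient")
  if (length(unique(records$source)) != 1L)
    stopf("patient_tkv expects records of a single source")
  per_scan <- numeric(0)
  for (sc in sort(unique(records$scan_index))) {
    sub <- records[records$scan_index == sc, ]
    l <- sub$volume_mL[sub$side == "left"]
    r <- sub$volume_mL[sub$side == "right"]
    if (length(l) != 1L || length(r) != 1L)
      stopf("patient %s scan %d: missing %s kidney volume",
            records$patient_id[1], sc,
            if (length(l) != 1L) "left" else "right")
    per_scan[as.character(sc)] <- l + r
  }
  list(patient_id = records$patient_id[1], source = records$source[1],
       tkv_mL = mean(per_scan), n_observations = length(per_scan),
       per_scan_mL = per_scan)
}

#' Patient TKV table for a whole record set
#'
#' @param records a [volume_records()] table (any number of patients and
#'   sources).
#' @return data.frame with patient_id, source, tkv_mL, n_observations.
#' @export
patient_tkv_table <- function(records) {
  out <- list()
  for (src in unique(records$source)) {
    for (pid in unique(records$patient_id[records$source == src])) {
      t <- patient_tkv(records[records$patient_id == pid &
                                 records$source == src, ])
      out[[length(out) + 1L]] <-
        data.frame(patient_id = t$patient_id, source = t$source,
                   tkv_mL = t$tkv_mL, n_observations = t$n_observations)
    }
  }
  do.call(rbind, out)
}

#' Interscan variability of repeated kidney sweeps
#'
#' Each kidney contributes the absolute deviations of its three scan volumes
#' from their mean; the statistic is the average of all such absolute
#' deviations across kidneys.  Kidneys without exactly three scans are
#' excluded with a warning.
#'
#' @param records a [volume_records()] table of one source.
#' @return mean absolute deviation in mL.
#' @export
interscan_variability <- function(records) {
  devs <- numeric(0)
  excluded <- 0L
  for (pid in unique(records$patient_id)) {
    for (sd_ in c("left", "right")) {
      v <- records$volume_mL[records$patient_id == pid &
                               records$side == sd_]
      if (length(v) == 0L) next
      if (length(v) != 3L) { excluded <- excluded + 1L; next }
      devs <- c(devs, abs(v - mean(v)))
    }
  }
  if (excluded > 0L)
    warning(sprintf("%d kidney(s) without exactly 3 scans excluded",
                    excluded), call. = FALSE)
  if (length(devs) == 0L) stopf("no complete scan triples found")
  mean(devs)
}
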