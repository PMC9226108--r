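#' Mayo imaging classification of ADPKD severity
#'
#' Assigns the 1A--1E severity class from age, height and total kidney
#' volume.  Height-adjusted TKV is `htTKV = tkv_mL / height_m` (mL/m); the
#' class boundaries at age `A` follow the modelled annual kidney-growth
#' bands of the classification tool, `150 * (1 + r)^A` mL/m for growth rates
#' r = 1.5, 3, 4.5 and 6 %/yr.  Bands are half-open `[lower, upper)`, so a
#' value exactly on a boundary is assigned to the higher (more severe)
#' class.  The model domain is typical bilateral disease in adults; ages of
#' 15 or below are classified but flagged out-of-domain.
#'
#' @param age years (> 0).
#' @param height_m height in metres (> 0).
#' @param tkv_mL total kidney volume in mL (>= 0).
#' @return list of class `mayo_class`: `label` (factor 1A..1E), `httkv`
#'   (mL/m), `boundaries` (the four thresholds at this age, mL/m) and
#'   `out_of_domain`.
#' @export
mayo_classify <- function(age, height_m, tkv_mL) {
  if (age <= 0 || height_m <= 0 || tkv_mL < 0)
    stopf("age and height must be positive and TKV non-negative")
  httkv <- tkv_mL / height_m
  b <- mayo_thresholds(age)
  label <- mayo_labels()[sum(httkv >= b) + 1L]
  structure(list(label = factor(label, levels = mayo_labels()),
                 httkv = httkv, boundaries = b,
                 out_of_domain = age <= 15),
            class = "mayo_class")
}

# Class boundaries (mL/m) at a given age; isolated so an alternative
# parameterization can be swapped in.
mayo_thresholds <- function(age, baseline = 150,
                            rates = c(0.015, 0.03, 0.045, 0.06)) {
  stats::setNames(baseline * (1 + rates)^age, c("1B", "1C", "1D", "1E"))
}

mayo_labels <- function() c("1A", "1B", "1C", "1D", "1E")

#' @export
print.mayo_class <- function(x, ...) {
  cat(sprintf("Mayo class %s (htTKV %.1f mL/m)%s\n", as.character(x$label),
              x$httkv, if (x$out_of_domain) " [out of model domain]" else ""))
  invisible(x)
}

#' Classify a cohort and cross-tabulate sources
#'
#' Applies [mayo_classify()] per patient and TKV source, tabulates class
#' counts per source, and cross-tabulates each pair of sources with a
#' per-patient discordance list.
#'
#' @param tkv_table data.frame with columns patient_id, source, tkv_mL
#'   (e.g. from [patient_tkv_table()]).
#' @param demographics data.frame with columns patient_id, age, height_m;
#'   every patient in `tkv_table` must be present.
#' @return list with `per_patient` (data.frame patient_id, source, httkv,
#'   label), `counts` (sources x 1A..1E table, rows summing to cohort
#'   size), `cross_tabs` (named list of 5x5 tables per source pair) and
#'   `discordant` (data.frame of per-patient disagreements).
#' @export
classify_cohort <- function(tkv_table, demographics) {
  missing <- setdiff(tkv_table$patient_id, demographics$patient_id)
  if (length(missing) > 0)
    stopf("patients missing from demographics: %s",
          paste(unique(missing), collapse = ", "))
  rows <- lapply(seq_len(nrow(tkv_table)), function(i) {
    pid <- tkv_table$patient_id[i]
    dg <- demographics[demographics$patient_id == pid, ][1, ]
    mc <- mayo_classify(dg$age, dg$height_m, tkv_table$tkv_mL[i])
    data.frame(patient_id = pid, source = tkv_table$source[i],
               httkv = mc$httkv, label = as.character(mc$label),
               stringsAsFactors = FALSE)
  })
  pp <- do.call(rbind, rows)
  pp$label <- factor(pp$label, levels = mayo_labels())
  counts <- table(source = pp$source, class = pp$label)
  sources <- unique(pp$source)
  cross <- list(); disc <- list()
  if (length(sources) > 1) {
    for (i in seq_along(sources)) for (j in seq_along(sources)) {
      if (i >= j) next
      a <- pp[pp$source == sources[i], ]
      b <- pp[pp$source == sources[j], ]
      common <- intersect(a$patient_id, b$patient_id)
      la <- a$label[match(common, a$patient_id)]
      lb <- b$label[match(common, b$patient_id)]
      key <- paste(sources[i], "vs", sources[j])
      cross[[key]] <- table(la, lb, dnn = c(sources[i], sources[j]))
      sel <- as.character(la) != as.character(lb)
      if (any(sel))
        disc[[key]] <- data.frame(pair = key, patient_id = common[sel],
                                  label_a = as.character(la[sel]),
                                  label_b = as.character(lb[sel]),
                                  stringsAsFactors = FALSE)
    }
  }
  list(per_patient = pp, counts = counts, cross_tabs = cross,
       discordant = if (length(disc) > 0) do.call(rbind, disc) else
         data.frame(pair = character(), patient_id = character(),
                    label_a = character(), label_b = character()))
}
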