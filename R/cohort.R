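#' Read a cohort demographics table
#'
#' Expects a CSV with header `study_id,sex,age,height_m,bmi`.  The packaged
#' ADPKD study cohort (22 patients) ships as
#' `system.file("extdata", "adpkd_cohort.csv", package = "sonotkv")`.
#'
#' @param path CSV file; defaults to the packaged cohort.
#' @return validated data.frame of class `cohort_table`.
#' @export
read_cohort <- function(path = system.file("extdata", "adpkd_cohort.csv",
                                           package = "sonotkv")) {
  # sex must be read as character: an all-female column would otherwise be
  # parsed as the logical F
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sex = "character"))
  need <- c("study_id", "sex", "age", "height_m", "bmi")
  if (!all(need %in% names(df)))
    stopf("cohort table must have columns %s", paste(need, collapse = ", "))
  bad <- which(duplicated(df$study_id) | !df$sex %in% c("M", "F") |
                 df$height_m <= 0.5 | df$height_m >= 2.5 |
                 df$age <= 0 | df$age >= 120 | df$bmi <= 0)
  if (length(bad) > 0)
    stopf("invalid cohort rows: %s", paste(df$study_id[bad], collapse = ", "))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Demographic summary of a cohort
#'
#' Reports the counts and central statistics used in study descriptions:
#' sex counts and percent female, mean/median/min/max age, mean/median
#' height, and BMI category counts.  The BMI bands are contiguous half-open
#' intervals: normal `[18.5, 25)`, overweight `[25, 30)`, obese `>= 30`
#' kg/m^2, with underweight (`< 18.5`) counted separately when present.
#' Medians follow the usual convention (middle value, or mean of the two
#' middle values for even n).
#'
#' @param table a [read_cohort()] table.
#' @return list of class `cohort_summary`.
#' @export
summarize_cohort <- function(table = read_cohort()) {
  if (nrow(table) == 0) stopf("cohort table is empty")
  s <- list(n = nrow(table),
            n_female = sum(table$sex == "F"),
            n_male = sum(table$sex == "M"),
            pct_female = 100 * mean(table$sex == "F"),
            mean_age = mean(table$age),
            median_age = stats::median(table$age),
            min_age = min(table$age),
            max_age = max(table$age),
            mean_height = mean(table$height_m),
            median_height = stats::median(table$height_m),
            bmi_underweight = sum(table$bmi < 18.5),
            bmi_normal = sum(table$bmi >= 18.5 & table$bmi < 25),
            bmi_overweight = sum(table$bmi >= 25 & table$bmi < 30),
            bmi_obese = sum(table$bmi >= 30))
  class(s) <- "cohort_summary"
  s
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients: %d F / %d M (%.0f%% female)\n",
              x$n, x$n_female, x$n_male, x$pct_female))
  cat(sprintf("  age: mean %.0f, median %.0f, range %d-%d years\n",
              x$mean_age, x$median_age, x$min_age, x$max_age))
  cat(sprintf("  height: mean %.2f m, median %.2f m\n",
              round_half_up(x$mean_height, 2),
              round_half_up(x$median_height, 2)))
  cat(sprintf("  BMI: %d normal, %d overweight, %d obese%s\n",
              x$bmi_normal, x$bmi_overweight, x$bmi_obese,
              if (x$bmi_underweight > 0)
                sprintf(", %d underweight", x$bmi_underweight) else ""))
  invisible(x)
}
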