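cohort_required_cols <- c("patient_id", "surgery_date", "chemo_last_cycle_start",
                          "targeted_therapy", "superficiality",
                          "steatosis_fraction", "diameter_baseline_mm",
                          "diameter_presurgery_mm")

#' Read a cohort covariate table
#'
#' One row per lesion. Dates are ISO-8601 and parsed to `Date`;
#' `targeted_therapy` to logical. Basic range checks mirror the data
#' contract: non-negative diameters, steatosis fraction in 0-100, surgery
#' not before the last chemotherapy cycle.
#'
#' @param path CSV path with a header row.
#' @return Data frame of class `cohort_table`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_required_cols, names(df))
  if (length(missing))
    stop_rimquant("cohort table missing required column(s): ",
                  paste(missing, collapse = ", "), class = "rimquant_validation")
  df$surgery_date <- as.Date(df$surgery_date)
  df$chemo_last_cycle_start <- as.Date(
    ifelse(df$chemo_last_cycle_start %in% c("", "NA"), NA,
           df$chemo_last_cycle_start))
  df$targeted_therapy <- as.logical(df$targeted_therapy)
  if (any(df$diameter_baseline_mm < 0, na.rm = TRUE) ||
      any(df$diameter_presurgery_mm < 0, na.rm = TRUE))
    stop_rimquant("diameters must be non-negative", class = "rimquant_validation")
  if (any(df$steatosis_fraction < 0 | df$steatosis_fraction > 100, na.rm = TRUE))
    stop_rimquant("steatosis_fraction must lie in [0, 100]",
                  class = "rimquant_validation")
  gap <- as.numeric(df$surgery_date - df$chemo_last_cycle_start)
  if (any(!is.na(gap) & gap < 0))
    stop_rimquant("surgery_date precedes chemo_last_cycle_start",
                  class = "rimquant_validation")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write per-lesion results
#'
#' Emits one CSV row per lesion with the four fluorescence parameters, the
#' background area, the provenance flags and the loaf ids used, plus any
#' covariate columns present. `read_results()` restores the exact table, so
#' write-then-read is the identity.
#'
#' @param records Data frame, one row per lesion (e.g. from
#'   [lesion_records()]).
#' @param path Output CSV path (or `.json` for a JSON rendering).
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  df <- as.data.frame(records)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA,
                         na = "null", dataframe = "rows")
  } else {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read back a per-lesion results table written by [write_results()]
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("background_pooled", "stasis_override",
                          "excluded_insufficient_tissue", "pretreated",
                          "targeted_therapy"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  for (col in intersect(c("surgery_date", "chemo_last_cycle_start"), names(df)))
    df[[col]] <- as.Date(df[[col]])
  df
}

#' Flatten lesion results into a per-lesion record table
#'
#' Joins each `lesion_result` to its cohort covariates and derives the
#' categorical covariates: pretreatment status, steatosis grade, RECIST
#' response class.
#'
#' @param results Named list of `lesion_result` objects; names are
#'   `patient_id`s matching the cohort table.
#' @param cohort A `cohort_table` from [read_cohort()] (or an equivalent
#'   data frame).
#' @return Data frame with one row per lesion: fluorescence parameters,
#'   flags, covariates and derived classes.
#' @export
lesion_records <- function(results, cohort) {
  stopifnot(!is.null(names(results)))
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    data.frame(patient_id = id, msfi_au = r$msfi_au, mbfi_au = r$mbfi_au,
               sbr = r$sbr, max_intensity_au = r$max_intensity_au,
               background_area_mm2 = r$background_area_mm2,
               background_pooled = isTRUE(r$flags$background_pooled),
               stasis_override = isTRUE(r$flags$stasis_override),
               excluded_insufficient_tissue =
                 isTRUE(r$flags$excluded_insufficient_tissue),
               loaf_ids_used = paste(r$loaf_ids_used, collapse = ";"))
  })
  res <- do.call(rbind, rows)
  merged <- merge(res, cohort, by = "patient_id", sort = FALSE)
  merged$pretreated <- is_pretreated(merged$chemo_last_cycle_start,
                                     merged$surgery_date)
  merged$steatosis_grade <- grade_steatosis(merged$steatosis_fraction)
  rec <- rep(NA_character_, nrow(merged))
  pre <- merged$pretreated & !is.na(merged$diameter_baseline_mm) &
    !is.na(merged$diameter_presurgery_mm)
  if (any(pre))
    rec[pre] <- as.character(classify_recist(merged$diameter_baseline_mm[pre],
                                             merged$diameter_presurgery_mm[pre])$class)
  merged$recist <- rec
  merged
}
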