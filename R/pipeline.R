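#' Build and validate a pipeline configuration
#'
#' File layout convention: each bread loaf is a grayscale TIFF named
#' `<patient_id>__<loaf_id>.tif` with a sibling `<patient_id>__<loaf_id>.geojson`
#' holding its annotations; the cohort covariates are one CSV.
#'
#' @param images_dir Directory of loaf TIFFs and GeoJSON annotations.
#' @param cohort_csv Path to the cohort covariate table.
#' @param out_dir Output directory (created if needed).
#' @param pixel_size_um,rim_mm,background_from_mm,min_background_mm2,max_scope
#'   Band-analysis parameters, see [quantify_specimen()].
#' @param stats A [cohort_config()].
#' @param seed Seed recorded for any simulation steps.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(images_dir, cohort_csv, out_dir,
                            pixel_size_um = 85, rim_mm = 3,
                            background_from_mm = 5, min_background_mm2 = 100,
                            max_scope = "tissue", stats = cohort_config(),
                            seed = 1L) {
  if (rim_mm <= 0 || background_from_mm <= 0 || min_background_mm2 <= 0 ||
      pixel_size_um <= 0)
    stop_rimquant("all numeric parameters must be positive",
                  class = "rimquant_config")
  if (rim_mm > background_from_mm)
    stop_rimquant("rim_mm must not exceed background_from_mm",
                  class = "rimquant_config")
  if (!max_scope %in% c("tissue", "image", "rim"))
    stop_rimquant("max_scope must be tissue, image or rim",
                  class = "rimquant_config")
  structure(list(images_dir = images_dir, cohort_csv = cohort_csv,
                 out_dir = out_dir, pixel_size_um = pixel_size_um,
                 rim_mm = rim_mm, background_from_mm = background_from_mm,
                 min_background_mm2 = min_background_mm2,
                 max_scope = max_scope, stats = stats, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments (the `stats$tests` map becomes the test-per-parameter
#'   configuration).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  stats <- if (!is.null(y$stats$tests))
    cohort_config(tests = unlist(y$stats$tests)) else cohort_config()
  y$stats <- NULL
  do.call(pipeline_config, c(y, list(stats = stats)))
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  plain <- lapply(unclass(config), function(v)
    if (is.list(v)) lapply(unclass(v), as.vector) else as.vector(v))
  yaml::write_yaml(plain, f)
  unname(tools::md5sum(f))
}

discover_specimens <- function(images_dir) {
  tifs <- sort(list.files(images_dir, pattern = "\\.tiff?$", full.names = TRUE))
  if (length(tifs) == 0L)
    stop_rimquant("no TIFF images found in ", images_dir, class = "rimquant_io")
  base <- sub("\\.tiff?$", "", basename(tifs))
  parts <- strsplit(base, "__", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop_rimquant("image name(s) not of the form <patient>__<loaf>.tif: ",
                  paste(basename(tifs)[bad], collapse = ", "),
                  class = "rimquant_io")
  data.frame(path = tifs,
             annotation = file.path(dirname(tifs), paste0(base, ".geojson")),
             patient_id = vapply(parts, `[`, "", 1L),
             loaf_id = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Run the full quantification and cohort-analysis pipeline
#'
#' For every patient: read the loaf images and annotations, select the
#' central loaf, build band masks, quantify, apply the stasis/override and
#' background-pooling rules; then join covariates, derive the clinical
#' classes, and run the statistical battery. Lesions that fail a hard
#' precondition are recorded as excluded with a reason code and the
#' pipeline continues. Identical inputs and configuration give
#' byte-identical `results.csv`.
#'
#' Outputs in `out_dir`: `results.csv` (per-lesion parameters, flags and
#' covariates), `report.json` (the statistics), `audit.json` (per-lesion
#' band pixel counts, flags, pooling order, exclusions, package version and
#' configuration hash).
#'
#' @param config A [pipeline_config()] or path to its YAML rendering.
#' @return Invisibly, a list with `records`, `report`, `audit` and the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- discover_specimens(config$images_dir)
  cohort <- read_cohort(config$cohort_csv)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list(); audits <- list(); exclusions <- list()
  for (pid in unique(manifest$patient_id)) {
    rows <- manifest[manifest$patient_id == pid, , drop = FALSE]
    out <- tryCatch({
      loaves <- lapply(seq_len(nrow(rows)), function(i) {
        img <- read_fluorescence_image(rows$path[i], config$pixel_size_um,
                                       "NIR", loaf_id = rows$loaf_id[i],
                                       specimen_id = pid)
        list(image = img, annotations = read_annotations(rows$annotation[i], img))
      })
      quantify_specimen(loaves, config$rim_mm, config$background_from_mm,
                        config$min_background_mm2, config$max_scope)
    }, rimquant_error = function(e) e)
    if (inherits(out, "rimquant_error")) {
      code <- if (inherits(out, "rimquant_missing_annotation"))
        "missing_annotation" else "processing_error"
      exclusions[[pid]] <- list(reason = code, message = conditionMessage(out))
      next
    }
    if (isTRUE(out$flags$excluded_insufficient_tissue))
      exclusions[[pid]] <- list(reason = "insufficient_tissue",
                                message = sprintf(
                                  "background area %.1f mm^2 below %g mm^2",
                                  out$background_area_mm2,
                                  config$min_background_mm2))
    results[[pid]] <- out
    audits[[pid]] <- attr(out, "audit")
  }
  if (length(results) == 0L)
    stop_rimquant("no lesion could be quantified", class = "rimquant_io")

  records <- lesion_records(results, cohort)
  report <- run_paper_analyses(records, config$stats)

  results_path <- file.path(config$out_dir, "results.csv")
  write_results(records, results_path)
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report_to_list(report), report_path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  audit <- list(package_version = as.character(utils::packageVersion("rimquant")),
                config = lapply(unclass(config), function(v)
                  if (inherits(v, "cohort_config")) unclass(v) else v),
                config_hash = config_hash(config),
                lesions = audits, exclusions = exclusions)
  audit_path <- file.path(config$out_dir, "audit.json")
  jsonlite::write_json(audit, audit_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(list(records = records, report = report, audit = audit,
                 paths = c(results = results_path, report = report_path,
                           audit = audit_path)))
}

# plain-list rendering of a cohort_report for JSON serialization
report_to_list <- function(report) {
  gc_list <- function(g) if (is.null(g)) NULL else
    list(parameter = g$parameter, groups = g$groups,
         summaries = lapply(g$summaries, unclass), test = g$test,
         statistic = g$statistic, p_value = g$p_value,
         p_display = format_p(g$p_value))
  fit_list <- function(f) if (is.null(f)) NULL else
    list(dependent = f$dependent, n = f$n, coefficients = f$coefficients)
  list(by_pretreatment = lapply(report$by_pretreatment, gc_list),
       by_superficiality = lapply(report$by_superficiality, gc_list),
       steatosis_mbfi = gc_list(report$steatosis_mbfi),
       spearman_size = report$spearman_size,
       ols = lapply(report$ols, fit_list),
       recist_descriptive = report$recist_descriptive,
       log = report$log)
}
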