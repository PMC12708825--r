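#' Polygonal approximation of an ellipse, in pixel coordinates
#'
#' @param center_px `(x, y)` center in pixels.
#' @param semi_axes_px `(a, b)` semi-axes in pixels.
#' @param n Number of vertices.
#' @return `n x 2` vertex matrix.
#' @export
ellipse_polygon <- function(center_px, semi_axes_px, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = center_px[1] + semi_axes_px[1] * cos(th),
        y = center_px[2] + semi_axes_px[2] * sin(th))
}

#' Specification of a synthetic bread-loaf phantom
#'
#' The phantom emulates the geometry of an ex vivo NIR slice: a
#' low-intensity tumor core, a peritumoral fluorescent rim whose intensity
#' decays exponentially with distance to the tumor, a noisy parenchymal
#' background, and optional stasis blobs of pooled dye. Outside the tumor
#' the noise-free intensity is `background_level + rim_amplitude *
#' exp(-d / rim_decay_lambda_mm)` with `d` the distance to the tumor in mm.
#'
#' Defaults paint an untreated-lesion phantom on a 280 x 380 grid of 85 µm
#' pixels (a 23.8 x 32.3 mm slice): background 0.104 a.u., rim amplitude
#' 2.2 a.u. with 1 mm decay — which puts the rim-band mean near 0.65 a.u.
#' and the maximum near 2.3 a.u., the magnitudes seen in untreated
#' patients.
#'
#' @param shape `(rows, cols)` grid size.
#' @param pixel_size_um Pixel size (default 85).
#' @param tumor_center_mm `(x, y)` tumor center in mm (default slice center).
#' @param tumor_semi_axes_mm Tumor ellipse semi-axes in mm.
#' @param tissue_semi_axes_mm Tissue (loaf) ellipse semi-axes in mm.
#' @param background_level Parenchymal level b, a.u.
#' @param tumor_core_level Intensity inside the tumor, a.u.
#' @param rim_amplitude Rim amplitude a, a.u. (0 allowed).
#' @param rim_decay_lambda_mm Rim decay length λ in mm, > 0.
#' @param noise_sd Additive Gaussian noise SD, a.u.; clipped at 0.
#' @param stasis_blobs List of `list(center_mm =, semi_axes_mm =, level =)`.
#' @param seed Optional RNG seed for reproducible noise.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(280L, 380L), pixel_size_um = 85,
                         tumor_center_mm = NULL,
                         tumor_semi_axes_mm = c(4, 3),
                         tissue_semi_axes_mm = c(14, 10.5),
                         background_level = 0.104, tumor_core_level = 0.05,
                         rim_amplitude = 2.2, rim_decay_lambda_mm = 1.0,
                         noise_sd = 0.02, stasis_blobs = list(),
                         seed = NULL) {
  px_mm <- pixel_size_um / 1000
  if (is.null(tumor_center_mm))
    tumor_center_mm <- c(shape[2] / 2, shape[1] / 2) * px_mm
  if (background_level < 0 || rim_amplitude < 0 || noise_sd < 0 ||
      rim_decay_lambda_mm <= 0 || tumor_core_level < 0)
    stop_rimquant("phantom levels must be non-negative and lambda positive",
                  class = "rimquant_validation")
  if (any(tumor_semi_axes_mm >= tissue_semi_axes_mm))
    stop_rimquant("tumor ellipse must lie strictly inside the tissue ellipse",
                  class = "rimquant_validation")
  structure(list(shape = as.integer(shape), pixel_size_um = pixel_size_um,
                 tumor_center_mm = tumor_center_mm,
                 tumor_semi_axes_mm = tumor_semi_axes_mm,
                 tissue_semi_axes_mm = tissue_semi_axes_mm,
                 background_level = background_level,
                 tumor_core_level = tumor_core_level,
                 rim_amplitude = rim_amplitude,
                 rim_decay_lambda_mm = rim_decay_lambda_mm,
                 noise_sd = noise_sd, stasis_blobs = stasis_blobs,
                 seed = seed),
            class = "phantom_spec")
}

#' Generate a synthetic bread-loaf phantom
#'
#' Builds tumor/tissue (and stasis) polygon annotations, rasterizes them
#' with the pipeline's own rasterizer, paints the noise-free intensity
#' model on those masks, then adds truncated-Gaussian noise. Because the
#' annotations are rasterized by the same rule the pipeline uses, the
#' analytic band means in the truth record refer to exactly the pixels the
#' pipeline will measure: with zero noise, measured MSFI equals
#' `msfi_expected` to machine precision.
#'
#' @param spec A [phantom_spec()].
#' @param rim_mm,background_from_mm Band thresholds used for the truth
#'   record's expected band means.
#' @return List with `image` ([fluorescence_image]), `annotations`
#'   ([annotation_set]) and `truth` (expected band means, band pixel
#'   counts, and the generating parameters).
#' @export
generate_phantom <- function(spec, rim_mm = 3, background_from_mm = 5) {
  stopifnot(inherits(spec, "phantom_spec"))
  px_mm <- spec$pixel_size_um / 1000
  to_px <- function(mm) mm / px_mm
  center_px <- to_px(spec$tumor_center_mm)
  tumor_poly <- ellipse_polygon(center_px, to_px(spec$tumor_semi_axes_mm), 96)
  tissue_poly <- ellipse_polygon(center_px, to_px(spec$tissue_semi_axes_mm), 128)
  stasis_polys <- lapply(spec$stasis_blobs, function(b)
    ellipse_polygon(to_px(b$center_mm), to_px(b$semi_axes_mm), 48))
  ann <- annotation_set(list(tumor_poly), list(tissue_poly), stasis_polys)

  tumor <- rasterize(ann$tumor, spec$shape)
  tissue <- rasterize(ann$tissue, spec$shape)
  d <- distance_to_tumor(tumor, spec$pixel_size_um)
  clean <- spec$background_level +
    spec$rim_amplitude * exp(-d / spec$rim_decay_lambda_mm)
  clean[tumor] <- spec$tumor_core_level
  for (i in seq_along(spec$stasis_blobs)) {
    blob <- rasterize(list(stasis_polys[[i]]), spec$shape) & !tumor
    clean[blob] <- clean[blob] + spec$stasis_blobs[[i]]$level
  }
  clean[!tissue] <- 0
  noisy <- with_seed(spec$seed, {
    if (spec$noise_sd > 0)
      pmax(clean + matrix(rnorm(length(clean), 0, spec$noise_sd),
                          nrow(clean)), 0)
    else clean
  })
  noisy[!tissue] <- 0

  masks <- build_band_masks(tumor, tissue, spec$pixel_size_um, rim_mm,
                            background_from_mm)
  band_mean <- function(m) if (any(m)) mean(clean[m]) else NA_real_
  truth <- list(
    msfi_expected = band_mean(masks$rim),
    mbfi_expected = band_mean(masks$background),
    sbr_expected = band_mean(masks$rim) / band_mean(masks$background),
    n_rim_pixels = sum(masks$rim),
    n_background_pixels = sum(masks$background),
    background_area_mm2 = mask_area_mm2(masks$background, spec$pixel_size_um),
    background_level = spec$background_level,
    rim_amplitude = spec$rim_amplitude,
    rim_decay_lambda_mm = spec$rim_decay_lambda_mm,
    noise_sd = spec$noise_sd,
    note = paste("synthetic phantom; rim width and decay are placeholder",
                 "parameters, not patient-derived"))
  list(image = fluorescence_image(noisy, spec$pixel_size_um, "NIR",
                                  loaf_id = "phantom-1",
                                  specimen_id = "phantom"),
       annotations = ann, truth = truth)
}

#' Generate a multi-loaf phantom specimen
#'
#' Emulates slicing one ellipsoidal lesion into several bread loaves: the
#' tumor cross-section is largest at the designated central loaf and
#' shrinks elliptically away from it. Optionally one loaf's tissue outline
#' is shrunk so its background area falls below 100 mm^2, to exercise the
#' background-pooling rule.
#'
#' @param spec A [phantom_spec()] for the central loaf.
#' @param n_loaves Number of loaves.
#' @param center_index Loaf holding the maximal cross-section.
#' @param small_background_index Optional loaf whose tissue is shrunk to
#'   starve its background below the pooling threshold.
#' @return List of `list(image =, annotations =, truth =)`, one per loaf.
#' @export
generate_multi_loaf_specimen <- function(spec, n_loaves,
                                         center_index = ceiling(n_loaves / 2),
                                         small_background_index = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), n_loaves >= 1,
            center_index >= 1, center_index <= n_loaves)
  lapply(seq_len(n_loaves), function(k) {
    # elliptical chord profile: relative half-thickness offset in [0, 1)
    rel <- abs(k - center_index) / max(n_loaves, 2)
    scale <- sqrt(max(1 - rel^2, 0.05))
    sp <- spec
    sp$tumor_semi_axes_mm <- spec$tumor_semi_axes_mm * scale
    if (!is.null(small_background_index) && k == small_background_index)
      sp$tissue_semi_axes_mm <- spec$tumor_semi_axes_mm * scale +
        c(5.6, 5.6)  # leaves only a sliver beyond the 5 mm background edge
    if (!is.null(spec$seed)) sp$seed <- spec$seed + k
    ph <- generate_phantom(sp)
    ph$image$loaf_id <- sprintf("loaf-%d", k)
    ph
  })
}

#' Specification of a synthetic patient cohort
#'
#' Emulates the structure of the study cohort: 10/32 chemotherapy
#' prevalence, 22/32 capsular lesions, tumor diameters normal with mean
#' 29.9 mm and SD 15.4 mm truncated at 5 mm, steatosis grades in 9:19:4:0
#' proportion. Fluorescence outcomes are a log-normal baseline (untreated
#' medians: MSFI 0.65, MBFI 0.104, SBR 6.08, maximum 1.9 a.u. before the
#' size effect) plus planted linear effects — chemotherapy lowers MSFI by
#' 0.36, SBR by 3.8 and the maximum by 0.72; each cm of tumor adds 0.25 to
#' the maximum — plus Gaussian residual noise.
#'
#' @param n_patients Cohort size.
#' @param chemo_prevalence,capsular_prevalence Bernoulli probabilities.
#' @param diameter_mean_mm,diameter_sd_mm,diameter_min_mm Diameter model.
#' @param steatosis_probs Probabilities for grades none/mild/moderate/severe.
#' @param baseline_medians Named medians of the log-normal baselines.
#' @param baseline_sdlog Log-scale SD of the baselines.
#' @param effects Named list of planted coefficients:
#'   `chemo` (per-outcome additive shift) and `size` (per-cm slope).
#' @param residual_sd Named Gaussian residual SDs.
#' @param seed RNG seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 32L,
                        chemo_prevalence = 10 / 32,
                        capsular_prevalence = 22 / 32,
                        diameter_mean_mm = 29.9, diameter_sd_mm = 15.4,
                        diameter_min_mm = 5,
                        steatosis_probs = c(none = 9, mild = 19,
                                            moderate = 4, severe = 0) / 32,
                        baseline_medians = c(msfi_au = 0.65, mbfi_au = 0.104,
                                             sbr = 6.08, max_intensity_au = 1.9),
                        baseline_sdlog = c(msfi_au = 0.45, mbfi_au = 0.4,
                                           sbr = 0.45, max_intensity_au = 0.25),
                        effects = list(
                          chemo = c(msfi_au = -0.36, mbfi_au = 0, sbr = -3.8,
                                    max_intensity_au = -0.72),
                          size = c(msfi_au = 0, mbfi_au = 0, sbr = 0,
                                   max_intensity_au = 0.25)),
                        residual_sd = c(msfi_au = 0.08, mbfi_au = 0.01,
                                        sbr = 0.8, max_intensity_au = 0.25),
                        seed = NULL) {
  stopifnot(n_patients >= 1, abs(sum(steatosis_probs) - 1) < 1e-9,
            chemo_prevalence >= 0, chemo_prevalence <= 1,
            capsular_prevalence >= 0, capsular_prevalence <= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic lesion-record cohort with planted effects
#'
#' Draws covariates and fluorescence outcomes per the specification; the
#' truth record stores the planted coefficients so recovery by
#' [fit_ols()] can be scored. Outcomes are not truncated at zero: the
#' planted model is kept exactly linear so least-squares estimates are
#' unbiased (the deep null tail may dip below zero, which real intensities
#' cannot).
#'
#' @param spec A [cohort_spec()].
#' @return List with `records` (data frame shaped like
#'   [lesion_records()] output) and `truth` (planted coefficients).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    chemo <- rbinom(n, 1, spec$chemo_prevalence) == 1
    capsular <- rbinom(n, 1, spec$capsular_prevalence) == 1
    diam <- rnorm(n, spec$diameter_mean_mm, spec$diameter_sd_mm)
    # truncation at the minimum by redraw
    while (any(diam < spec$diameter_min_mm))
      diam[diam < spec$diameter_min_mm] <-
        rnorm(sum(diam < spec$diameter_min_mm), spec$diameter_mean_mm,
              spec$diameter_sd_mm)
    grade <- sample(names(spec$steatosis_probs), n, replace = TRUE,
                    prob = spec$steatosis_probs)
    # a representative fraction inside each grade's bin, for round-tripping
    frac <- c(none = 0, mild = 20, moderate = 50, severe = 80)[grade]
    size_cm <- diam / 10
    surgery <- as.Date("2021-06-15") + sample.int(300, n, replace = TRUE)
    chemo_date <- as.Date(ifelse(chemo, surgery - sample(20:80, n, replace = TRUE),
                                 NA), origin = "1970-01-01")
    # pretreated lesions shrink ~25% on average; untreated drift up slightly
    presurg <- diam * ifelse(chemo, runif(n, 0.6, 0.95), runif(n, 0.95, 1.15))
    params <- names(spec$baseline_medians)
    out <- list()
    for (p in params) {
      base <- rlnorm(n, meanlog = log(spec$baseline_medians[[p]]),
                     sdlog = spec$baseline_sdlog[[p]])
      out[[p]] <- base + spec$effects$chemo[[p]] * chemo +
        spec$effects$size[[p]] * size_cm +
        rnorm(n, 0, spec$residual_sd[[p]])
    }
    records <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      msfi_au = out$msfi_au, mbfi_au = out$mbfi_au, sbr = out$sbr,
      max_intensity_au = out$max_intensity_au,
      background_area_mm2 = round(runif(n, 110, 400), 2),
      background_pooled = FALSE, stasis_override = FALSE,
      excluded_insufficient_tissue = FALSE,
      loaf_ids_used = "loaf-1",
      surgery_date = surgery, chemo_last_cycle_start = chemo_date,
      targeted_therapy = chemo & rbinom(n, 1, 0.8) == 1,
      superficiality = ifelse(capsular, "capsular", "subcapsular"),
      steatosis_fraction = unname(frac),
      diameter_baseline_mm = diam, diameter_presurgery_mm = presurg,
      pretreated = chemo,
      steatosis_grade = factor(grade, levels = c("none", "mild", "moderate",
                                                 "severe"), ordered = TRUE),
      stringsAsFactors = FALSE)
    records$recist <- NA_character_
    records$recist[chemo] <- as.character(
      classify_recist(diam[chemo], presurg[chemo])$class)
    truth <- list(
      coefficients = lapply(setNames(params, params), function(p)
        c(pretreatment = unname(spec$effects$chemo[[p]]),
          superficiality = 0,
          size_cm = unname(spec$effects$size[[p]]))),
      chemo_prevalence = spec$chemo_prevalence,
      baseline_medians = spec$baseline_medians)
    list(records = records, truth = truth)
  })
}

#' Write a phantom to disk as TIFF + GeoJSON + truth manifest
#'
#' The image is quantized to 16-bit; the intensity scale (a.u. per
#' full-scale digital number) is recorded in the truth manifest so the
#' arbitrary-unit scale can be restored.
#'
#' @param phantom Output of [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @param basename File stem, e.g. `"P001__loaf-1"`.
#' @param scale Intensity mapped to full scale; fix it across a study so
#'   digital numbers are comparable between loaves (default: image maximum).
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir, basename, scale = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(basename, ".tif"))
  ann_path <- file.path(dir, paste0(basename, ".geojson"))
  truth_path <- file.path(dir, paste0(basename, ".truth.json"))
  scale <- write_fluorescence_image(phantom$image, img_path, scale = scale)
  write_annotations(phantom$annotations, ann_path)
  truth <- c(phantom$truth, list(intensity_scale_au_per_fullscale = scale,
                                 synthetic = TRUE))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, annotations = ann_path, truth = truth_path))
}
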