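new_lesion_result <- function(msfi, mbfi, sbr, max_intensity, background_area_mm2,
                              flags = list(background_pooled = FALSE,
                                           stasis_override = FALSE,
                                           excluded_insufficient_tissue = FALSE),
                              loaf_ids_used = character()) {
  structure(list(msfi_au = msfi, mbfi_au = mbfi, sbr = sbr,
                 max_intensity_au = max_intensity,
                 background_area_mm2 = background_area_mm2,
                 flags = flags, loaf_ids_used = loaf_ids_used),
            class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  cat("<lesion_result>\n")
  cat(sprintf("  MSFI %.4g a.u. | MBFI %s a.u. | SBR %s | max %.4g a.u.\n",
              x$msfi_au,
              if (is.na(x$mbfi_au)) "NA" else sprintf("%.4g", x$mbfi_au),
              if (is.na(x$sbr)) "NA" else sprintf("%.4g", x$sbr),
              x$max_intensity_au))
  cat(sprintf("  background area %.2f mm^2; loaves: %s\n",
              x$background_area_mm2, paste(x$loaf_ids_used, collapse = ", ")))
  on <- names(Filter(isTRUE, x$flags))
  cat("  flags:", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Quantify the fluorescence parameters of one bread loaf
#'
#' Computes the four fluorescence parameters over the predefined bands:
#' MSFI (mean over the rim), MBFI (mean over the background), SBR
#' (MSFI / MBFI), and the maximum intensity. The maximum is taken over the
#' tissue of the analyzed loaf by default; the whole frame or the rim alone
#' can be selected instead. An empty background yields `NA` MBFI/SBR and a
#' zero background area — exclusion or pooling is decided downstream.
#'
#' @param image A [fluorescence_image].
#' @param masks A `band_masks` object from [build_band_masks()].
#' @param max_scope Region over which the maximum intensity is taken:
#'   `"tissue"` (default), `"image"`, or `"rim"`.
#' @return A `lesion_result`.
#' @export
quantify_loaf <- function(image, masks, max_scope = c("tissue", "image", "rim")) {
  max_scope <- match.arg(max_scope)
  stopifnot(inherits(image, "fluorescence_image"), inherits(masks, "band_masks"),
            all(dim(image$pixels) == dim(masks$rim)))
  if (!any(masks$rim))
    stop_rimquant("no rim pixels", class = "rimquant_empty_rim")
  px <- image$pixels
  msfi <- mean(px[masks$rim])
  has_bg <- any(masks$background)
  mbfi <- if (has_bg) mean(px[masks$background]) else NA_real_
  sbr <- if (has_bg && mbfi > 0) msfi / mbfi else NA_real_
  tissue <- masks$tumor | masks$rim | masks$gap | masks$background
  mx <- switch(max_scope, tissue = max(px[tissue]), image = max(px),
               rim = max(px[masks$rim]))
  new_lesion_result(msfi, mbfi, sbr, mx,
                    mask_area_mm2(masks$background, masks$pixel_size_um),
                    loaf_ids_used = as.character(image$loaf_id))
}

#' Recalculate the background when ICG stasis contaminates the loaf
#'
#' Pooled (stasis) ICG inflates the background estimate. If the operator
#' drew a representative background-override region, MBFI is recomputed over
#' its intersection with tissue at background distance; otherwise, if stasis
#' polygons exist, MBFI is recomputed over the background with stasis pixels
#' subtracted. With neither annotation the result passes through unchanged.
#'
#' @param result A `lesion_result` from [quantify_loaf()].
#' @param image The [fluorescence_image] the result was computed from.
#' @param masks Its `band_masks`.
#' @param annotations The loaf's [annotation_set] (source of the stasis and
#'   override polygons).
#' @return The `lesion_result`, with MBFI/SBR revised and the
#'   `stasis_override` flag set when a recalculation occurred.
#' @export
apply_stasis_override <- function(result, image, masks, annotations) {
  stopifnot(inherits(result, "lesion_result"), inherits(annotations, "annotation_set"))
  shape <- dim(image$pixels)
  tissue <- masks$tumor | masks$rim | masks$gap | masks$background
  if (length(annotations$background_override) > 0L) {
    region <- rasterize(annotations$background_override, shape) & tissue &
      masks$dist_mm >= masks$background_from_mm
    if (!any(region))
      stop_rimquant("override region invalid: empty after intersection with ",
                    "tissue at background distance", class = "rimquant_override")
  } else if (length(annotations$stasis) > 0L) {
    region <- masks$background & !rasterize(annotations$stasis, shape)
    if (!any(region))
      stop_rimquant("override region invalid: stasis covers the whole background",
                    class = "rimquant_override")
  } else {
    return(result)
  }
  result$mbfi_au <- mean(image$pixels[region])
  result$sbr <- if (result$mbfi_au > 0) result$msfi_au / result$mbfi_au else NA_real_
  result$background_area_mm2 <- mask_area_mm2(region, masks$pixel_size_um)
  result$flags$stasis_override <- TRUE
  result
}

#' Pool background across bread loaves when healthy tissue is scarce
#'
#' When the analyzed loaf offers less than `min_area_mm2` of background
#' tissue, background pixels from the other loaves of the same specimen
#' (their own at-distance regions) are appended, in the given order, until
#' the cumulative area reaches the threshold; MBFI becomes the pooled pixel
#' mean. If all loaves together still fall short, the lesion is flagged
#' excluded and MBFI/SBR are withheld.
#'
#' @param result The primary loaf's `lesion_result`.
#' @param other_loaves List of `list(image =, masks =)` for the remaining
#'   loaves, in pooling order.
#' @param min_area_mm2 Required background area (default 100).
#' @return The revised `lesion_result`.
#' @export
pool_background <- function(result, other_loaves = list(), min_area_mm2 = 100) {
  stopifnot(inherits(result, "lesion_result"))
  if (!is.na(result$background_area_mm2) &&
      result$background_area_mm2 >= min_area_mm2) return(result)
  area <- result$background_area_mm2
  px2 <- NULL
  pooled <- numeric(0)
  for (lo in other_loaves) {
    stopifnot(inherits(lo$masks, "band_masks"))
    if (is.null(px2)) px2 <- (lo$masks$pixel_size_um / 1000)^2
    vals <- lo$image$pixels[lo$masks$background]
    if (length(vals) == 0L) next
    pooled <- c(pooled, vals)
    area <- area + mask_area_mm2(lo$masks$background, lo$masks$pixel_size_um)
    result$loaf_ids_used <- c(result$loaf_ids_used, as.character(lo$image$loaf_id))
    if (area >= min_area_mm2) break
  }
  if (area >= min_area_mm2) {
    if (is.null(px2)) px2 <- 1  # unreachable: area grew only via loaves
    n_primary <- if (result$background_area_mm2 > 0)
      round(result$background_area_mm2 / px2) else 0
    pooled_mean <- (n_primary * ifelse(n_primary > 0, result$mbfi_au, 0) +
                      sum(pooled)) / (n_primary + length(pooled))
    result$mbfi_au <- pooled_mean
    result$sbr <- if (pooled_mean > 0) result$msfi_au / pooled_mean else NA_real_
    result$background_area_mm2 <- area
    result$flags$background_pooled <- TRUE
  } else {
    result$flags$excluded_insufficient_tissue <- TRUE
    result$mbfi_au <- NA_real_
    result$sbr <- NA_real_
    result$background_area_mm2 <- area
  }
  result
}

#' Select the bread loaf at the center of the tumor
#'
#' The central cross-section of a roughly ellipsoidal lesion is the one with
#' the largest tumor area, so the loaf maximizing rasterized tumor area is
#' selected; ties break to the lowest index.
#'
#' @param loaves List of `list(image =, annotations =)` per loaf.
#' @return Integer index into `loaves`.
#' @export
select_central_loaf <- function(loaves) {
  areas <- vapply(loaves, function(lo) {
    if (!inherits(lo$annotations, "annotation_set") ||
        length(lo$annotations$tumor) == 0L) return(NA_real_)
    sum(rasterize(lo$annotations$tumor, dim(lo$image$pixels)))
  }, numeric(1))
  if (all(is.na(areas)))
    stop_rimquant("no loaf has a tumor annotation", class = "rimquant_missing_annotation")
  which.max(replace(areas, is.na(areas), -Inf))
}

#' Quantify one lesion from its bread loaves
#'
#' Full per-lesion procedure: select the central loaf, build its band
#' masks, quantify, apply the stasis/override recalculation, and pool
#' background from the remaining loaves if the central loaf offers less
#' than `min_background_mm2` of healthy tissue.
#'
#' @param loaves List of `list(image =, annotations =)`, one entry per loaf.
#' @param rim_mm,background_from_mm Band thresholds in mm.
#' @param min_background_mm2 Minimum healthy-tissue area for MBFI.
#' @param max_scope Passed to [quantify_loaf()].
#' @return A `lesion_result` with an attribute `central_loaf` (the index
#'   analyzed).
#' @export
quantify_specimen <- function(loaves, rim_mm = 3, background_from_mm = 5,
                              min_background_mm2 = 100,
                              max_scope = c("tissue", "image", "rim")) {
  max_scope <- match.arg(max_scope)
  ci <- select_central_loaf(loaves)
  build <- function(lo) {
    shape <- dim(lo$image$pixels)
    build_band_masks(rasterize(lo$annotations$tumor, shape),
                     rasterize(lo$annotations$tissue, shape),
                     lo$image$pixel_size_um, rim_mm, background_from_mm)
  }
  masks <- build(loaves[[ci]])
  res <- quantify_loaf(loaves[[ci]]$image, masks, max_scope)
  res <- apply_stasis_override(res, loaves[[ci]]$image, masks,
                               loaves[[ci]]$annotations)
  if (res$background_area_mm2 < min_background_mm2) {
    others <- lapply(loaves[-ci], function(lo)
      list(image = lo$image, masks = build(lo)))
    res <- pool_background(res, others, min_background_mm2)
  }
  attr(res, "central_loaf") <- ci
  attr(res, "audit") <- list(
    central_loaf = ci,
    band_pixels = vapply(c("tumor", "rim", "gap", "background"),
                         function(b) sum(masks[[b]]), numeric(1)),
    flags = res$flags, loaf_ids_used = res$loaf_ids_used)
  res
}
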