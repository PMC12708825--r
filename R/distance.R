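#' Euclidean distance to the tumor, in millimetres
#'
#' Computes, for every pixel, the Euclidean distance from its center to the
#' nearest tumor-pixel center, converted to mm through the pixel size.
#' Tumor pixels hold 0. The tumor is treated as its raster pixel set, not
#' its polygon outline, so the field is exactly checkable against an
#' all-pairs oracle. Backed by an exact Euclidean distance transform.
#'
#' @param tumor_mask Logical matrix; must contain at least one `TRUE`.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return Numeric matrix of distances in mm, same shape as `tumor_mask`.
#' @export
distance_to_tumor <- function(tumor_mask, pixel_size_um) {
  stopifnot(is.matrix(tumor_mask), is.logical(tumor_mask))
  if (!any(tumor_mask))
    stop_rimquant("empty tumor mask", class = "rimquant_empty_tumor")
  if (all(tumor_mask)) return(matrix(0, nrow(tumor_mask), ncol(tumor_mask)))
  # distmap measures each nonzero pixel's distance to the nearest zero pixel,
  # so the tumor is encoded as the zero set
  d <- EBImage::imageData(EBImage::distmap(ifelse(tumor_mask, 0, 1),
                                           metric = "euclidean"))
  d * (pixel_size_um / 1000)
}

#' Build distance-banded masks around the tumor
#'
#' Partitions the tissue into tumor, rim (tissue within `rim_mm` of the
#' tumor), an unassigned gap, and background (tissue at least
#' `background_from_mm` away). Both thresholds are inclusive; when they
#' coincide, a pixel exactly at the threshold is assigned to the rim so the
#' bands stay disjoint. Tumor pixels falling outside the tissue are
#' intersected away with a warning.
#'
#' @param tumor_mask,tissue_mask Logical matrices of the image shape.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param rim_mm Outer edge of the rim band (default 3 mm).
#' @param background_from_mm Inner edge of the background (default 5 mm).
#' @return An object of class `band_masks` with logical matrices `tumor`,
#'   `rim`, `gap`, `background`, the distance field `dist_mm`, and the
#'   band parameters.
#' @export
build_band_masks <- function(tumor_mask, tissue_mask, pixel_size_um,
                             rim_mm = 3.0, background_from_mm = 5.0) {
  stopifnot(is.matrix(tumor_mask), is.matrix(tissue_mask),
            all(dim(tumor_mask) == dim(tissue_mask)))
  if (rim_mm > background_from_mm)
    stop_rimquant("rim_mm must not exceed background_from_mm",
                  class = "rimquant_validation")
  n_outside <- sum(tumor_mask & !tissue_mask)
  if (n_outside > 0) {
    warning(n_outside, " tumor pixel(s) outside tissue intersected away",
            call. = FALSE)
    tumor_mask <- tumor_mask & tissue_mask
  }
  d <- distance_to_tumor(tumor_mask, pixel_size_um)
  nontumor <- tissue_mask & !tumor_mask
  rim <- nontumor & d <= rim_mm
  background <- nontumor & !rim & d >= background_from_mm
  gap <- nontumor & !rim & !background
  structure(list(tumor = tumor_mask, rim = rim, gap = gap,
                 background = background, dist_mm = d,
                 pixel_size_um = pixel_size_um, rim_mm = rim_mm,
                 background_from_mm = background_from_mm),
            class = "band_masks")
}

#' @export
print.band_masks <- function(x, ...) {
  px2 <- (x$pixel_size_um / 1000)^2
  cat(sprintf("<band_masks> rim <= %g mm, background >= %g mm (%.0f um px)\n",
              x$rim_mm, x$background_from_mm, x$pixel_size_um))
  for (b in c("tumor", "rim", "gap", "background"))
    cat(sprintf("  %-10s %7d px  %8.2f mm^2\n", b, sum(x[[b]]), sum(x[[b]]) * px2))
  invisible(x)
}

#' Display band masks
#'
#' Renders tumor, rim, gap and background as four intensity levels.
#'
#' @param x A `band_masks` object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.band_masks <- function(x, ...) {
  z <- matrix(0, nrow(x$tumor), ncol(x$tumor))
  z[x$background] <- 1; z[x$gap] <- 2; z[x$rim] <- 3; z[x$tumor] <- 4
  d <- dim(z)
  graphics::image(x = seq_len(d[2]) - 0.5, y = seq_len(d[1]) - 0.5,
                  z = t(z[d[1]:1, , drop = FALSE]),
                  col = c("grey95", "steelblue", "grey70", "orange", "firebrick"),
                  xlab = "x (px)", ylab = "y (px)", asp = 1,
                  main = "bands: tumor / rim / gap / background", ...)
  invisible(x)
}
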