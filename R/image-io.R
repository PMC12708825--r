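#' Construct a fluorescence image
#'
#' A `fluorescence_image` wraps a 2-D grid of non-negative intensities in
#' arbitrary units (a.u.) together with its physical pixel size and channel
#' metadata. Rows run down the image (y), columns run right (x), origin at
#' the top-left; this matches the frame in which annotations are drawn.
#'
#' @param pixels Numeric matrix of intensities, all `>= 0`.
#' @param pixel_size_um Physical edge length of a pixel in micrometres
#'   (default 85, the resolution of the back-table imaging system).
#' @param channel `"NIR"` or `"WHITE"`.
#' @param loaf_id,specimen_id Optional identifiers of the bread loaf and the
#'   resected specimen it was cut from.
#' @return An object of class `fluorescence_image`.
#' @export
fluorescence_image <- function(pixels, pixel_size_um = 85,
                               channel = c("NIR", "WHITE"),
                               loaf_id = NA_character_,
                               specimen_id = NA_character_) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_rimquant("pixels must be a numeric matrix", class = "rimquant_validation")
  if (any(dim(pixels) < 1L))
    stop_rimquant("image must be at least 1 x 1", class = "rimquant_validation")
  if (anyNA(pixels) || any(pixels < 0))
    stop_rimquant("intensities must be non-negative and non-missing",
                  class = "rimquant_validation")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop_rimquant("pixel_size_um must be a single positive number",
                  class = "rimquant_validation")
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel = channel, loaf_id = as.character(loaf_id),
                 specimen_id = as.character(specimen_id)),
            class = "fluorescence_image")
}

#' Read a grayscale TIFF as a fluorescence image
#'
#' Intensities are read as stored: integer rasters become doubles with no
#' rescaling, so the arbitrary-unit scale of the device export is preserved
#' bit-exactly.
#'
#' @param path Path to a single-plane grayscale TIFF (8/16-bit integer or
#'   32-bit float).
#' @inheritParams fluorescence_image
#' @return A [fluorescence_image].
#' @export
read_fluorescence_image <- function(path, pixel_size_um = 85,
                                    channel = c("NIR", "WHITE"),
                                    loaf_id = NA_character_,
                                    specimen_id = NA_character_) {
  channel <- match.arg(channel)
  if (!file.exists(path))
    stop_rimquant("file not found: ", path, class = "rimquant_io")
  raw <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (length(raw) != 1L)
    stop_rimquant("multi-plane TIFF (", length(raw),
                  " planes); expected a single grayscale plane",
                  class = "rimquant_format")
  raw <- raw[[1L]]
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3L] == 1L) raw <- raw[, , 1L]
    else stop_rimquant("color TIFF with ", dim(raw)[3L],
                       " channels along the third axis; expected grayscale",
                       class = "rimquant_format")
  }
  fluorescence_image(raw, pixel_size_um = pixel_size_um, channel = channel,
                     loaf_id = loaf_id, specimen_id = specimen_id)
}

#' Write a fluorescence image to TIFF
#'
#' Intensities are quantized to unsigned integers of the requested depth.
#' `scale` is the intensity value mapped to the maximum digital number; it
#' defaults to the image maximum, and is returned (invisibly) so callers can
#' record it, since TIFF integer storage cannot carry the a.u. scale itself.
#'
#' @param image A [fluorescence_image].
#' @param path Output path.
#' @param bits_per_sample 8 or 16.
#' @param scale Intensity mapped to full scale; default `max(pixels)`
#'   (a flat zero image uses scale 1).
#' @return Invisibly, the scale used (a.u. per full-scale digital number).
#' @export
write_fluorescence_image <- function(image, path, bits_per_sample = 16L,
                                     scale = NULL) {
  stopifnot(inherits(image, "fluorescence_image"))
  if (is.null(scale)) scale <- max(image$pixels, 1e-12)
  tiff::writeTIFF(pmin(image$pixels / scale, 1),
                  path, bits.per.sample = as.integer(bits_per_sample))
  invisible(scale)
}

#' @export
print.fluorescence_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fluorescence_image> %d x %d px (%.0f um/px), channel %s\n",
              d[1], d[2], x$pixel_size_um, x$channel))
  cat(sprintf("  intensity range [%.4g, %.4g] a.u.; specimen %s, loaf %s\n",
              min(x$pixels), max(x$pixels), x$specimen_id, x$loaf_id))
  invisible(x)
}

#' Display a fluorescence image
#'
#' @param x A [fluorescence_image].
#' @param ... Passed to [graphics::image()].
#' @export
plot.fluorescence_image <- function(x, ...) {
  d <- dim(x$pixels)
  graphics::image(x = seq_len(d[2]) - 0.5, y = seq_len(d[1]) - 0.5,
                  z = t(x$pixels[d[1]:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (px)", ylab = "y (px)", asp = 1,
                  main = sprintf("%s channel (a.u.)", x$channel), ...)
  invisible(x)
}
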