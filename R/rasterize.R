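#' Rasterize polygons to a pixel mask
#'
#' A pixel belongs to the mask iff its center lies inside the union of the
#' polygons under the even-odd rule. With 0-based pixel indices the center
#' of pixel (row, col) sits at x = col + 0.5, y = row + 0.5 (origin
#' top-left, y down); in the returned 1-based R matrix that is entry
#' `[row + 1, col + 1]`. Vertices outside the frame are allowed; pixels
#' outside the frame are simply absent from the mask.
#'
#' @param polygons List of `n x 2` polygon vertex matrices (x, y), or a
#'   single matrix. An empty list yields an all-`FALSE` mask.
#' @param image A [fluorescence_image] supplying the grid, or an integer
#'   vector `c(nrow, ncol)`.
#' @return Logical matrix of the image dimensions.
#' @export
rasterize <- function(polygons, image) {
  shape <- if (inherits(image, "fluorescence_image")) dim(image$pixels)
           else as.integer(image)
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  if (is.matrix(polygons)) polygons <- list(polygons)
  mask <- matrix(FALSE, shape[1], shape[2])
  if (length(polygons) == 0L) return(mask)
  xc <- seq_len(shape[2]) - 0.5    # pixel-center x per column
  for (poly in polygons) {
    pmask <- matrix(FALSE, shape[1], shape[2])
    poly <- as.matrix(poly)
    x1 <- poly[, 1]; y1 <- poly[, 2]
    x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
    keep <- y1 != y2                 # horizontal edges never cross a scanline
    x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
    if (length(x1) == 0L) next
    ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
    for (r in seq_len(shape[1])) {
      yc <- r - 0.5
      # half-open span [ylo, yhi) counts each vertex-crossing exactly once
      hit <- ylo <= yc & yc < yhi
      if (!any(hit)) next
      xcross <- x1[hit] + (yc - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit])
      # even-odd: inside iff an odd number of crossings lie right of the center
      ncross <- length(xcross) - findInterval(xc, sort(xcross))
      pmask[r, ] <- ncross %% 2L == 1L
    }
    mask <- mask | pmask    # union across polygons
  }
  mask
}

# mask area in mm^2 given the pixel size
mask_area_mm2 <- function(mask, pixel_size_um) {
  sum(mask) * (pixel_size_um / 1000)^2
}
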