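#' Default annotation label synonyms
#'
#' Annotation tools emit varied class names; this table maps them
#' (case-insensitively) onto the four roles the pipeline understands. Extend
#' or replace it via the `synonyms` argument of [read_annotations()].
#'
#' @return Named character vector: names are lower-case labels as found in
#'   the file, values are one of `"tumor"`, `"tissue"`, `"stasis"`,
#'   `"background_override"`.
#' @export
default_label_synonyms <- function() {
  c(tumor = "tumor", tumour = "tumor", lesion = "tumor", metastasis = "tumor",
    tissue = "tissue", liver = "tissue", parenchyma = "tissue",
    loaf = "tissue", "bread loaf" = "tissue",
    stasis = "stasis", "icg stasis" = "stasis", artifact = "stasis",
    background_override = "background_override",
    "background override" = "background_override",
    "representative background" = "background_override",
    background = "background_override")
}

#' Construct an annotation set
#'
#' Polygons are `n x 2` matrices of `(x, y)` vertices in image pixel
#' coordinates (origin top-left, x rightward, y downward). Closing the ring
#' is implicit: the last vertex is joined back to the first.
#'
#' @param tumor,tissue Lists of polygons (each may also be given as a single
#'   matrix). At least one of each is required for band analysis.
#' @param stasis,background_override Optional polygon lists.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(tumor, tissue, stasis = list(),
                           background_override = list()) {
  as_polys <- function(p, what) {
    if (is.matrix(p)) p <- list(p)
    if (!is.list(p)) stop_rimquant(what, " must be a list of polygons",
                                   class = "rimquant_validation")
    lapply(p, function(m) {
      m <- as.matrix(m)
      if (ncol(m) != 2L || nrow(m) < 3L || anyNA(m))
        stop_rimquant(what, " polygons must be n x 2 matrices with n >= 3",
                      class = "rimquant_validation")
      storage.mode(m) <- "double"
      colnames(m) <- c("x", "y")
      m
    })
  }
  structure(list(tumor = as_polys(tumor, "tumor"),
                 tissue = as_polys(tissue, "tissue"),
                 stasis = as_polys(stasis, "stasis"),
                 background_override = as_polys(background_override,
                                                "background_override")),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(paste0("<annotation_set> %d tumor, %d tissue, %d stasis, ",
                     "%d background-override polygon(s)\n"),
              length(x$tumor), length(x$tissue), length(x$stasis),
              length(x$background_override)))
  invisible(x)
}

#' Read tumor/tissue annotations from a GeoJSON FeatureCollection
#'
#' Each feature's classification is read from `classification.name` (the
#' digital-pathology convention) or, failing that, `properties.label`, and
#' mapped case-insensitively through the synonym table. Features with
#' unknown labels are ignored with a warning. Vertices outside the image
#' frame are retained; clipping happens at rasterization.
#'
#' @param path Path to a GeoJSON file.
#' @param image Optional [fluorescence_image]; unused for parsing but kept
#'   so call sites can assert the frame the polygons refer to.
#' @param synonyms Label synonym table, see [default_label_synonyms()].
#' @return An [annotation_set].
#' @export
read_annotations <- function(path, image = NULL,
                             synonyms = default_label_synonyms()) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else stop_rimquant("not a GeoJSON FeatureCollection",
                              class = "rimquant_format")
  groups <- list(tumor = list(), tissue = list(), stasis = list(),
                 background_override = list())
  for (f in feats) {
    lab <- f$properties$classification$name
    if (is.null(lab)) lab <- f$properties$label
    if (is.null(lab)) lab <- f$properties$name
    role <- if (!is.null(lab)) unname(synonyms[tolower(lab)]) else NA_character_
    if (is.null(lab) || is.na(role)) {
      warning("ignoring feature with unknown label: ",
              if (is.null(lab)) "<none>" else lab, call. = FALSE)
      next
    }
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      { warning("ignoring non-polygon geometry: ", geom$type, call. = FALSE)
        next })
    for (poly in rings) {
      # exterior ring only; interior rings (holes) are not produced by the
      # annotation workflow and are ignored with a warning
      if (length(poly) > 1L)
        warning("polygon interior rings ignored", call. = FALSE)
      ring <- poly[[1L]]
      m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      # GeoJSON rings repeat the first vertex; drop the duplicate
      if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      groups[[role]] <- c(groups[[role]], list(m))
    }
  }
  if (length(groups$tumor) == 0L)
    stop_rimquant("missing tumor annotation", class = "rimquant_missing_annotation")
  if (length(groups$tissue) == 0L)
    stop_rimquant("missing tissue annotation", class = "rimquant_missing_annotation")
  annotation_set(groups$tumor, groups$tissue, groups$stasis,
                 groups$background_override)
}

#' Write an annotation set as GeoJSON
#'
#' Inverse of [read_annotations()]; used by the phantom generator so that
#' synthetic annotations round-trip through the same reader as real ones.
#'
#' @param annotations An [annotation_set].
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  label_for <- c(tumor = "Tumor", tissue = "Tissue", stasis = "Stasis",
                 background_override = "Background override")
  feats <- list()
  for (role in names(label_for)) {
    for (poly in annotations[[role]]) {
      ring <- rbind(poly, poly[1, , drop = FALSE])
      coords <- lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
      feats <- c(feats, list(list(
        type = "Feature",
        properties = list(classification = list(name = label_for[[role]])),
        geometry = list(type = "Polygon", coordinates = list(coords)))))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
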