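# Independent brute-force oracles used across the suite. These deliberately
# take the slow, obvious route so they share no code path with the package.

# even-odd point-in-polygon by angle-free crossing count, one point at a time
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# exhaustive per-pixel-center rasterization of a polygon union (even-odd per
# polygon, OR across polygons)
oracle_rasterize <- function(polygons, shape) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  mask <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) for (c in seq_len(shape[2])) {
    px <- c - 0.5; py <- r - 0.5
    ins <- FALSE
    for (poly in polygons)
      ins <- ins || oracle_point_in_polygon(px, py, poly)
    mask[r, c] <- ins
  }
  mask
}

# all-pairs minimum center-to-center distance to the tumor set, in mm:
# the full |pixels| x |tumor| distance matrix is formed and minimized per row
oracle_distance_mm <- function(tumor_mask, pixel_size_um) {
  shape <- dim(tumor_mask)
  tum <- which(tumor_mask, arr.ind = TRUE)
  all_rc <- expand.grid(row = seq_len(shape[1]), col = seq_len(shape[2]))
  d2 <- outer(all_rc$row, tum[, 1], "-")^2 + outer(all_rc$col, tum[, 2], "-")^2
  matrix(sqrt(apply(d2, 1, min)), shape[1], shape[2]) * pixel_size_um / 1000
}

# full enumeration of the Mann-Whitney U null; two-sided p as twice the
# smaller tail. U is computed by direct pair counting, not rank sums.
oracle_mw_exact_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x); n <- length(vals)
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) u <- u + sum(ai > b) + 0.5 * sum(ai == b)
    u
  }
  u_obs <- u_of(x, y)
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, function(ix) u_of(vals[ix], vals[-ix]))
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# random blobby masks for oracle-equivalence checks: a few seed pixels dilated
# by random radii gives connected, irregular regions
random_mask <- function(shape, n_seeds = 3, max_r = 6) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (k in seq_len(n_seeds)) {
    r0 <- sample.int(shape[1], 1); c0 <- sample.int(shape[2], 1)
    rad <- runif(1, 1, max_r)
    rr <- outer(seq_len(shape[1]) - r0, rep(1, shape[2]))
    cc <- outer(rep(1, shape[1]), seq_len(shape[2]) - c0)
    m <- m | (rr^2 + cc^2 <= rad^2)
  }
  m
}

# minimal valid phantom kept small so mask/EDT tests stay fast; any
# phantom_spec argument may be overridden
small_phantom_spec <- function(...) {
  args <- utils::modifyList(list(shape = c(140L, 180L), pixel_size_um = 170,
                                 tumor_semi_axes_mm = c(4, 3),
                                 tissue_semi_axes_mm = c(14, 10.5)),
                            list(...))
  do.call(phantom_spec, args)
}

# flat synthetic image on an arbitrary mask layout for hand-value tests
flat_image <- function(value, shape, pixel_size_um = 1000) {
  fluorescence_image(matrix(value, shape[1], shape[2]),
                     pixel_size_um = pixel_size_um)
}
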