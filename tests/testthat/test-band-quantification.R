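test_that("distance to tumor has exact Euclidean geometry", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  d <- distance_to_tumor(m, pixel_size_um = 1000)  # 1 mm pixels
  expect_equal(d[3, 3], 0)
  expect_equal(d[2, 3], 1); expect_equal(d[3, 4], 1)
  expect_equal(d[2, 2], sqrt(2)); expect_equal(d[4, 4], sqrt(2))
  expect_equal(d[1, 1], 2 * sqrt(2))

  expect_equal(distance_to_tumor(matrix(TRUE, 4, 6), 85), matrix(0, 4, 6))
  expect_error(distance_to_tumor(matrix(FALSE, 3, 3), 85),
               class = "rimquant_empty_tumor")
})

test_that("distance field equals the all-pairs brute-force oracle", {
  set.seed(7)
  for (rep in 1:20) {
    m <- random_mask(c(16, 16), n_seeds = sample(1:4, 1), max_r = 4)
    if (!any(m)) m[8, 8] <- TRUE
    expect_equal(distance_to_tumor(m, 85), oracle_distance_mm(m, 85))
  }
})

test_that("band masks partition tissue with the lattice geometry of the bands", {
  # single tumor pixel on 1 mm lattice: rim = lattice points with 0 < d <= 3
  tumor <- matrix(FALSE, 21, 21); tumor[11, 11] <- TRUE
  tissue <- matrix(TRUE, 21, 21)
  bm <- build_band_masks(tumor, tissue, pixel_size_um = 1000,
                         rim_mm = 3, background_from_mm = 5)
  expect_equal(sum(bm$rim), 28)        # 29 lattice points in the disc incl. center
  expect_equal(sum(bm$tumor), 1)
  # partition: disjoint and covering
  total <- bm$tumor + bm$rim + bm$gap + bm$background
  expect_true(all(total[tissue] == 1))
  expect_true(all(total[!tissue] == 0))
  # band distance invariants
  expect_true(all(bm$dist_mm[bm$rim] <= 3))
  expect_true(all(bm$dist_mm[bm$background] >= 5))
  expect_true(all(bm$dist_mm[bm$gap] > 3 & bm$dist_mm[bm$gap] < 5))
})

test_that("coincident thresholds leave no gap and degenerate tissue no background", {
  tumor <- matrix(FALSE, 15, 15); tumor[8, 8] <- TRUE
  tissue <- matrix(TRUE, 15, 15)
  bm <- build_band_masks(tumor, tissue, 1000, rim_mm = 3, background_from_mm = 3)
  expect_equal(sum(bm$gap), 0)
  expect_equal(bm$rim | bm$background, tissue & !tumor)
  expect_equal(sum(bm$rim & bm$background), 0)

  # tissue entirely within 3 mm of the tumor: background empty
  small <- matrix(FALSE, 15, 15); small[6:10, 6:10] <- TRUE
  bm2 <- build_band_masks(tumor, small, 1000)
  expect_equal(sum(bm2$background), 0)
  expect_error(build_band_masks(tumor, tissue, 1000, rim_mm = 5,
                                background_from_mm = 3),
               class = "rimquant_validation")
  expect_warning(build_band_masks(matrix(TRUE, 15, 15), small, 1000),
                 "outside tissue")
})

test_that("band masks equal a brute-force construction on random instances", {
  set.seed(99)
  for (rep in 1:30) {
    shape <- c(sample(16:48, 1), sample(16:48, 1))
    tumor <- random_mask(shape, 2, 4)
    tissue <- random_mask(shape, 4, 14) | tumor
    if (!any(tumor)) tumor[shape[1] %/% 2, shape[2] %/% 2] <- TRUE
    px <- sample(c(250, 500, 1000), 1)
    bm <- build_band_masks(tumor, tissue, px)
    d <- oracle_distance_mm(tumor, px)
    nontumor <- tissue & !tumor
    expect_equal(bm$rim, nontumor & d <= 3)
    expect_equal(bm$background, nontumor & d >= 5)
    expect_equal(bm$gap, nontumor & d > 3 & d < 5)
  }
})

test_that("growing rim_mm never shrinks the rim; growing background_from_mm never grows background", {
  set.seed(13)
  tumor <- random_mask(c(40, 40), 1, 3)
  tissue <- random_mask(c(40, 40), 3, 16) | tumor
  prev_rim <- 0
  for (rmm in c(1, 2, 3, 4)) {
    bm <- build_band_masks(tumor, tissue, 500, rim_mm = rmm,
                           background_from_mm = 6)
    expect_gte(sum(bm$rim), prev_rim)
    prev_rim <- sum(bm$rim)
  }
  prev_bg <- Inf
  for (bmm in c(4, 5, 6, 8)) {
    bm <- build_band_masks(tumor, tissue, 500, rim_mm = 3,
                           background_from_mm = bmm)
    expect_lte(sum(bm$background), prev_bg)
    prev_bg <- sum(bm$background)
  }
})

# small hand-built layout: 8x8, tumor pixel block, 1 mm pixels
hand_layout <- function() {
  tumor <- matrix(FALSE, 9, 9); tumor[5, 5] <- TRUE
  tissue <- matrix(TRUE, 9, 9)
  build_band_masks(tumor, tissue, 1000)
}

test_that("loaf quantification computes the four parameters from the bands", {
  bm <- hand_layout()
  # flat field: all four parameters collapse and SBR is exactly 1
  img <- flat_image(2.5, c(9, 9))
  r <- quantify_loaf(img, bm)
  expect_equal(r$msfi_au, 2.5); expect_equal(r$mbfi_au, 2.5)
  expect_equal(r$sbr, 1); expect_equal(r$max_intensity_au, 2.5)

  # hand means: rim {2,4}, background all 1
  px <- matrix(1, 9, 9)
  rim_idx <- which(bm$rim)
  px[rim_idx] <- 1
  px[rim_idx[1]] <- 2; px[rim_idx[2]] <- 4
  px[bm$rim][-(1:2)] <- 3  # keep rim mean = 3 regardless of rim size
  img2 <- fluorescence_image(px, 1000)
  r2 <- quantify_loaf(img2, bm)
  expect_equal(r2$msfi_au, 3)
  expect_equal(r2$mbfi_au, 1)
  expect_equal(r2$sbr, 3)

  # homogeneity: scaling intensities by c scales msfi/mbfi/max, leaves sbr
  r2c <- quantify_loaf(fluorescence_image(px * 7, 1000), bm)
  expect_equal(r2c$msfi_au, 7 * r2$msfi_au)
  expect_equal(r2c$mbfi_au, 7 * r2$mbfi_au)
  expect_equal(r2c$max_intensity_au, 7 * r2$max_intensity_au)
  expect_equal(r2c$sbr, r2$sbr)

  # max scope: a hot pixel outside tissue counts only for scope "image"
  tumor2 <- matrix(FALSE, 9, 9); tumor2[5, 4] <- TRUE
  tissue2 <- matrix(FALSE, 9, 9); tissue2[, 1:7] <- TRUE
  bm2 <- build_band_masks(tumor2, tissue2, 1000)
  px3 <- matrix(1, 9, 9); px3[1, 9] <- 99   # outside the tissue columns
  expect_equal(quantify_loaf(fluorescence_image(px3, 1000), bm2,
                             max_scope = "tissue")$max_intensity_au, 1)
  expect_equal(quantify_loaf(fluorescence_image(px3, 1000), bm2,
                             max_scope = "image")$max_intensity_au, 99)
})

test_that("background area converts pixel counts at 85 um to mm2 across the 100 mm2 rule", {
  px2 <- (85 / 1000)^2
  expect_gte(13841 * px2, 100)        # 100.0018 mm^2: meets the rule
  expect_lt(13840 * px2, 100)         # 99.99 mm^2: fails it
  # and quantify_loaf reports exactly that conversion
  bm <- hand_layout()
  bm$pixel_size_um <- 85
  r <- quantify_loaf(flat_image(1, c(9, 9), 85), bm)
  expect_equal(r$background_area_mm2, sum(bm$background) * px2)
})

test_that("stasis subtraction and background override recover the true background", {
  bm <- hand_layout()
  px <- matrix(1, 9, 9)
  # contaminate half the background with a value-10 blob
  bg_idx <- which(bm$background)
  blob <- bg_idx[seq_len(length(bg_idx) %/% 2)]
  px[blob] <- 10
  img <- fluorescence_image(px, 1000)
  naive <- quantify_loaf(img, bm)
  expect_gt(naive$mbfi_au, 5)

  # stasis polygon covering the blob pixels -> subtraction restores mean 1
  blob_rc <- arrayInd(blob, c(9, 9))
  stasis_polys <- lapply(seq_len(nrow(blob_rc)), function(i) {
    x0 <- blob_rc[i, 2] - 1; y0 <- blob_rc[i, 1] - 1
    rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1))
  })
  ann <- annotation_set(tumor = rbind(c(4, 4), c(5, 4), c(5, 5), c(4, 5)),
                        tissue = rbind(c(0, 0), c(9, 0), c(9, 9), c(0, 9)),
                        stasis = stasis_polys)
  fixed <- apply_stasis_override(naive, img, bm, ann)
  expect_equal(fixed$mbfi_au, 1)
  expect_true(fixed$flags$stasis_override)
  expect_equal(fixed$sbr, fixed$msfi_au)

  # explicit override region wins over stasis subtraction
  clean_rc <- arrayInd(setdiff(bg_idx, blob)[1], c(9, 9))
  ov <- rbind(c(clean_rc[2] - 1, clean_rc[1] - 1),
              c(clean_rc[2], clean_rc[1] - 1),
              c(clean_rc[2], clean_rc[1]),
              c(clean_rc[2] - 1, clean_rc[1]))
  px[bg_idx] <- 1.2
  px[blob] <- 10   # blob still contaminates; override pixel is outside it
  img2 <- fluorescence_image(px, 1000)
  ann_ov <- annotation_set(ann$tumor, ann$tissue,
                           background_override = list(ov))
  r_ov <- apply_stasis_override(quantify_loaf(img2, bm), img2, bm, ann_ov)
  expect_equal(r_ov$mbfi_au, 1.2)
  expect_true(r_ov$flags$stasis_override)

  # no stasis, no override: identity
  plain <- apply_stasis_override(naive, img, bm,
                                 annotation_set(ann$tumor, ann$tissue))
  expect_identical(plain, naive)

  # override entirely outside the background distance is invalid
  bad <- annotation_set(ann$tumor, ann$tissue,
                        background_override =
                          list(rbind(c(4, 4), c(5, 4), c(5, 5), c(4, 5))))
  expect_error(apply_stasis_override(naive, img, bm, bad),
               class = "rimquant_override")
})

test_that("background pooling follows the 100 mm2 rule with area-weighted means", {
  bm <- hand_layout()           # 1 mm pixels
  img <- flat_image(1, c(9, 9))
  primary <- quantify_loaf(img, bm)

  # already sufficient: untouched
  kept <- pool_background(primary, list(), min_area_mm2 = 10)
  expect_identical(kept, primary)

  # pooled mean equals the mean over concatenated pixels (area weighting)
  n1 <- sum(bm$background)
  other <- list(image = flat_image(2, c(9, 9)), masks = bm)
  pooled <- pool_background(primary, list(other), min_area_mm2 = 2 * n1)
  expect_equal(pooled$mbfi_au, (n1 * 1 + n1 * 2) / (2 * n1))
  expect_true(pooled$flags$background_pooled)
  expect_equal(pooled$background_area_mm2, 2 * n1)

  # spec-sheet magnitudes: 40 mm2 at mean 1 plus 80 mm2 at mean 2 -> 5/3
  pa <- primary; pa$background_area_mm2 <- 40; pa$mbfi_au <- 1
  big <- matrix(FALSE, 20, 20); big[1:8, 1:10] <- TRUE  # 80 px of background
  bm2 <- hand_layout()
  bm2_big <- list(tumor = matrix(FALSE, 20, 20), rim = matrix(FALSE, 20, 20),
                  gap = matrix(FALSE, 20, 20), background = big,
                  dist_mm = matrix(10, 20, 20), pixel_size_um = 1000,
                  rim_mm = 3, background_from_mm = 5)
  class(bm2_big) <- "band_masks"
  lo2 <- list(image = flat_image(2, c(20, 20)), masks = bm2_big)
  po <- pool_background(pa, list(lo2), min_area_mm2 = 100)
  expect_equal(po$mbfi_au, (40 * 1 + 80 * 2) / 120, tolerance = 1e-12)
  expect_equal(po$background_area_mm2, 120)

  # everything together below threshold: excluded, values withheld
  short <- pool_background(pa, list(), min_area_mm2 = 100)
  expect_true(short$flags$excluded_insufficient_tissue)
  expect_true(is.na(short$mbfi_au))
  expect_true(is.na(short$sbr))
})

test_that("central loaf selection maximizes tumor cross-section with stable ties", {
  mk_loaf <- function(side) {
    sq <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
    tissue <- rbind(c(0, 0), c(30, 0), c(30, 30), c(0, 30))
    list(image = flat_image(1, c(30, 30)),
         annotations = annotation_set(sq, tissue))
  }
  expect_equal(select_central_loaf(list(mk_loaf(3), mk_loaf(8), mk_loaf(5))), 2)
  expect_equal(select_central_loaf(list(mk_loaf(4))), 1)
  expect_equal(select_central_loaf(list(mk_loaf(6), mk_loaf(6))), 1)
  no_tumor <- list(image = flat_image(1, c(30, 30)),
                   annotations = structure(list(tumor = list(),
                                                tissue = list(),
                                                stasis = list(),
                                                background_override = list()),
                                           class = "annotation_set"))
  expect_error(select_central_loaf(list(no_tumor)),
               class = "rimquant_missing_annotation")
})
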