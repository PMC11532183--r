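test_that("ECA is the collagen/tissue pixel ratio", {
  m <- matrix(FALSE, 40, 25)
  tissue <- m; tissue[1:40, 1:25] <- TRUE  # 1000 tissue px
  collagen <- m; collagen[1:10, 1:10] <- TRUE  # 100 collagen px
  seg <- collagen_segmentation(tissue, collagen, matrix(0, 40, 25))
  expect_equal(compute_eca(seg), 10.0)
  seg_all <- collagen_segmentation(tissue, tissue, matrix(0, 40, 25))
  expect_equal(compute_eca(seg_all), 100.0)
  expect_error(compute_eca(collagen_segmentation(m, m, matrix(0, 40, 25))),
               "empty")
})

test_that("ECA equals a brute-force counting oracle on random masks", {
  set.seed(42)
  for (i in 1:10) {
    mk <- random_masks(60, 80)
    if (!any(mk$tissue)) next
    seg <- make_seg(matrix(0, 60, 80), mk$tissue, mk$collagen)
    brute <- 0L
    for (px in which(mk$collagen)) brute <- brute + 1L
    expect_identical(compute_eca(seg), 100 * brute / sum(mk$tissue))
  }
})

test_that("EnC is 0 on a constant field and bounded by log(bins)", {
  seg <- make_seg(matrix(0.7, 64, 64))
  expect_equal(compute_enc(seg), 0)
  set.seed(1)
  segr <- make_seg(matrix(runif(64 * 64), 64, 64))
  p <- feature_params()
  expect_lte(compute_enc(segr, p), log(p$entropy_bins))
  expect_gte(compute_enc(segr, p), 0)
  # base-2 option
  p2 <- feature_params(entropy_log_base = "2")
  expect_lte(compute_enc(segr, p2), log2(p2$entropy_bins))
})

test_that("a window evenly split between two occupied bins gives log 2", {
  od <- matrix(c(0, 0, 1, 1), 2, 2)   # two columns at two OD levels
  seg <- make_seg(od)
  p <- feature_params(entropy_window_px = 3)
  H <- local_entropy_map(seg, p)
  expect_equal(unique(as.vector(H)), log(2))
  expect_equal(compute_enc(seg, p), log(2))
})

test_that("EnC increases from constant to equal-mixture two-level field", {
  const <- make_seg(matrix(0.5, 48, 48))
  mixed <- make_seg(matrix(c(0, 1), 48, 48))  # alternating rows
  p <- feature_params()
  expect_gt(compute_enc(mixed, p), compute_enc(const, p))
})

test_that("EnC matches the naive sliding-window oracle", {
  set.seed(7)
  od <- matrix(runif(128 * 128, 0, 2), 128, 128)
  tissue <- matrix(runif(128 * 128) < 0.85, 128, 128)
  seg <- make_seg(od, tissue)
  p <- feature_params()
  expect_equal(compute_enc(seg, p),
               enc_oracle(od, tissue, p$entropy_window_px, p$entropy_bins),
               tolerance = 1e-9)
  # collagen support option
  collagen <- tissue & matrix(runif(128 * 128) < 0.2, 128, 128)
  segc <- make_seg(od, tissue, collagen)
  pc <- feature_params(entropy_support = "collagen")
  expect_equal(compute_enc(segc, pc),
               enc_oracle(od, tissue, p$entropy_window_px, p$entropy_bins,
                          support = collagen),
               tolerance = 1e-9)
})

test_that("ROI tiling arithmetic and per-ROI values are correct", {
  tissue <- matrix(TRUE, 64, 64)
  collagen <- tissue
  seg <- collagen_segmentation(tissue, collagen, matrix(0.3, 64, 64))
  rf <- compute_roi_features(seg)
  expect_identical(dim(rf$grids$collagen_fraction), c(2L, 2L))  # 4 ROIs
  expect_equal(as.vector(rf$grids$collagen_fraction), rep(1, 4))
  # co-occurrence energy of a constant ROI is exactly 1
  expect_equal(as.vector(rf$grids$glcm_energy), rep(1, 4))
  expect_equal(as.vector(rf$grids$glcm_contrast), rep(0, 4))
})

test_that("ROI exclusion flags low-tissue tiles and can reject all", {
  tissue <- matrix(FALSE, 64, 64)
  tissue[1:32, 1:32] <- TRUE           # one full-tissue ROI
  tissue[33:40, 33:36] <- TRUE         # one 3%-tissue ROI
  seg <- collagen_segmentation(tissue, tissue & FALSE, matrix(0, 64, 64))
  rf <- compute_roi_features(seg)
  expect_identical(rf$included, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  sparse <- collagen_segmentation(tissue & FALSE | diag(64) > 0,
                                  matrix(FALSE, 64, 64), matrix(0, 64, 64))
  expect_error(compute_roi_features(sparse), "roi_min_tissue_fraction")
})

test_that("tissue-weighted ROI collagen fractions conserve global ECA", {
  set.seed(13)
  for (i in 1:5) {
    mk <- random_masks(96, 96)
    seg <- make_seg(matrix(runif(96 * 96), 96, 96), mk$tissue, mk$collagen)
    rf <- compute_roi_features(seg, feature_params(roi_min_tissue_fraction = 0))
    sel <- rf$tissue_px > 0
    wmean <- sum(rf$grids$collagen_fraction[sel] * rf$tissue_px[sel]) /
      sum(rf$tissue_px[sel])
    expect_equal(wmean, compute_eca(seg) / 100, tolerance = 1e-9)
  }
})

test_that("biopsy_features assembles the documented battery", {
  sl <- generate_slide(synthetic_spec(256, 256,
                                      target_collagen_fraction = 0.08,
                                      seed = 9))
  seg <- segment_collagen(as_slide_image(sl))
  bf <- biopsy_features(seg, slide_id = "sy9")
  reg <- feature_registry()
  expect_gte(length(bf$extended), 28)
  expect_setequal(names(bf$extended),
                  setdiff(reg$feature, c("eca_percent", "enc")))
  expect_true(bf$eca_percent >= 0 && bf$eca_percent <= 100)
  expect_lte(bf$enc, log(8))
})

test_that("heatmap overlay matches the image size and colormap order", {
  sl <- generate_slide(synthetic_spec(256, 256, seed = 3))
  img <- as_slide_image(sl)
  grid <- matrix(as.numeric(1:64), 8, 8)
  hm <- render_heatmap(img, grid, "demo", alpha = 1)
  expect_identical(dim(hm$image), dim(img$pixels))
  # monotone grid -> pixel colors follow the viridis lookup exactly
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")))
  lo <- hm$image[1, 1, ]                   # cell with the lowest value
  hi <- hm$image[256, 256, ]               # cell with the highest value
  expect_equal(as.numeric(lo), as.numeric(pal[1, ]))
  expect_equal(as.numeric(hi), as.numeric(pal[256, ]))
  # all-equal grid -> a single overlay color
  hm1 <- render_heatmap(img, matrix(5, 8, 8), alpha = 1)
  cols <- unique(matrix(hm1$image, ncol = 3))
  expect_identical(nrow(cols), 1L)
  # NA/excluded cells stay transparent (original pixels)
  grid[1, 1] <- NA
  hm2 <- render_heatmap(img, grid, alpha = 0.5)
  expect_identical(hm2$image[1:32, 1:32, ], img$pixels[1:32, 1:32, ])
  # shape validation
  expect_error(render_heatmap(img, matrix(1, 3, 3)), "grid shape")
})
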