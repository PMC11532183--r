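#' Feature-extraction parameters
#'
#' Controls the two spatial scales of feature extraction: the per-pixel local
#' entropy used for EnC and the non-overlapping square ROIs used for the
#' extended battery and heatmaps.
#'
#' @param roi_px ROI side in pixels (default 32).
#' @param roi_min_tissue_fraction ROIs whose tissue fraction falls below this
#'   are excluded from slide-level summaries (default 0.5); biopsy fragments
#'   have ragged borders.
#' @param entropy_window_px Odd side of the square neighborhood for local
#'   entropy (default 9).
#' @param entropy_bins Number of OD quantization bins (default 8), spanning
#'   the slide's tissue OD range.
#' @param entropy_log_base `"e"` (natural log, default) or `"2"`.
#' @param entropy_support `"tissue"` (default) or `"collagen"`: the pixel set
#'   over which local entropies are averaged into EnC.
#' @return An object of class `feature_params`.
#' @export
feature_params <- function(roi_px = 32L, roi_min_tissue_fraction = 0.5,
                           entropy_window_px = 9L, entropy_bins = 8L,
                           entropy_log_base = c("e", "2"),
                           entropy_support = c("tissue", "collagen")) {
  .fq_check_number(roi_px, "roi_px", 1, Inf, integer = TRUE)
  .fq_check_number(roi_min_tissue_fraction, "roi_min_tissue_fraction", 0, 1)
  .fq_check_number(entropy_window_px, "entropy_window_px", 1, Inf,
                   integer = TRUE)
  if (entropy_window_px %% 2L == 0L)
    .fq_stop("`entropy_window_px` must be odd")
  .fq_check_number(entropy_bins, "entropy_bins", 2, Inf, integer = TRUE)
  entropy_log_base <- match.arg(as.character(entropy_log_base[1L]),
                                c("e", "2"))
  entropy_support <- match.arg(entropy_support)
  structure(list(
    roi_px = as.integer(roi_px),
    roi_min_tissue_fraction = roi_min_tissue_fraction,
    entropy_window_px = as.integer(entropy_window_px),
    entropy_bins = as.integer(entropy_bins),
    entropy_log_base = entropy_log_base,
    entropy_support = entropy_support
  ), class = "feature_params")
}

.fq_log_base <- function(params) if (params$entropy_log_base == "2") 2 else exp(1)

#' Estimated Collagen Area (ECA)
#'
#' The percentage of tissue pixels that are Sirius-Red-positive collagen:
#' `100 * count(collagen) / count(tissue)`.
#'
#' @param seg A [collagen_segmentation()].
#' @return ECA in percent, in \[0, 100\].
#' @export
compute_eca <- function(seg) {
  stopifnot(inherits(seg, "collagen_segmentation"))
  nt <- sum(seg$tissue_mask)
  if (nt == 0L) .fq_stop("ECA undefined: tissue mask is empty")
  100 * sum(seg$collagen_mask) / nt
}

#' Per-pixel local entropy of the SR optical density
#'
#' Quantizes the SR-OD map into `entropy_bins` equal-width bins spanning the
#' slide's tissue OD range, then computes for every pixel the Shannon entropy
#' of the bin histogram over the `entropy_window_px` square neighborhood
#' (clipped at the image border), counting only tissue pixels. Computed with
#' summed-area tables in O(h * w * bins).
#'
#' @inheritParams compute_eca
#' @param params A [feature_params()].
#' @return Numeric matrix of local entropies; `NA` where the window contains
#'   no tissue.
#' @export
local_entropy_map <- function(seg, params = feature_params()) {
  stopifnot(inherits(seg, "collagen_segmentation"))
  tissue <- seg$tissue_mask
  od <- seg$sr_od
  r <- (params$entropy_window_px - 1L) %/% 2L
  rng <- if (any(tissue)) range(od[tissue]) else c(0, 0)
  q <- .fq_quantize(od, params$entropy_bins, rng[1L], rng[2L])
  total <- .fq_box_sum(tissue * 1, r)
  H <- matrix(0, nrow(od), ncol(od))
  for (b in seq_len(params$entropy_bins)) {
    cb <- .fq_box_sum((q == b & tissue) * 1, r)
    p <- ifelse(total > 0, cb / pmax(total, 1), 0)
    H <- H - ifelse(p > 0, p * log(p, base = .fq_log_base(params)), 0)
  }
  H[total == 0] <- NA_real_
  H
}

#' Entropy of Collagen (EnC)
#'
#' A textural parameter encoding the randomness of SR optical-density values
#' with respect to their neighborhood: the mean of [local_entropy_map()] over
#' the support pixels (tissue by default). A perfectly uniform OD field over
#' tissue yields 0; the maximum is `log(entropy_bins)` in the configured
#' base.
#'
#' @inheritParams local_entropy_map
#' @return A non-negative number, at most `log(entropy_bins)`.
#' @export
compute_enc <- function(seg, params = feature_params()) {
  support <- if (params$entropy_support == "collagen") seg$collagen_mask
             else seg$tissue_mask
  if (!any(support))
    .fq_stop("EnC undefined: %s support mask is empty", params$entropy_support)
  H <- local_entropy_map(seg, params)
  mean(H[support])
}

# --- ROI battery ------------------------------------------------------------

# GLCM features over a quantized tile, offsets (0,1) and (1,0), symmetric,
# averaged; pairs restricted to tissue pixels. Constant tiles give
# contrast 0, energy 1, homogeneity 1, correlation 1 (degenerate-sd
# convention).
.fq_glcm <- function(q, tissue, levels) {
  h <- nrow(q); w <- ncol(q)
  counts <- numeric(levels * levels)
  add_pairs <- function(a, b, ta, tb) {
    ok <- ta & tb
    if (!any(ok)) return(invisible())
    i <- a[ok]; j <- b[ok]
    idx <- c((i - 1L) * levels + j, (j - 1L) * levels + i)  # symmetric
    counts <<- counts + tabulate(idx, nbins = levels * levels)
    invisible()
  }
  if (w >= 2L) add_pairs(q[, -w, drop = FALSE], q[, -1L, drop = FALSE],
                         tissue[, -w, drop = FALSE], tissue[, -1L, drop = FALSE])
  if (h >= 2L) add_pairs(q[-h, , drop = FALSE], q[-1L, , drop = FALSE],
                         tissue[-h, , drop = FALSE], tissue[-1L, , drop = FALSE])
  tot <- sum(counts)
  if (tot == 0) return(c(contrast = NA_real_, energy = NA_real_,
                         homogeneity = NA_real_, correlation = NA_real_))
  P <- matrix(counts / tot, levels, levels, byrow = TRUE)
  ii <- row(P); jj <- col(P)
  mu_i <- sum(ii * P); mu_j <- sum(jj * P)
  sd_i <- sqrt(sum((ii - mu_i)^2 * P)); sd_j <- sqrt(sum((jj - mu_j)^2 * P))
  corr <- if (sd_i < 1e-12 || sd_j < 1e-12) 1 else
    sum((ii - mu_i) * (jj - mu_j) * P) / (sd_i * sd_j)
  c(contrast = sum((ii - jj)^2 * P),
    energy = sum(P^2),
    homogeneity = sum(P / (1 + abs(ii - jj))),
    correlation = corr)
}

# Count of 4-connectivity boundary pixels of a mask (image border counts as
# outside).
.fq_perimeter_px <- function(mask) {
  if (!any(mask)) return(0L)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  up <- pad[1:h, 2:(w + 1L)]; dn <- pad[3:(h + 2L), 2:(w + 1L)]
  lf <- pad[2:(h + 1L), 1:w]; rt <- pad[2:(h + 1L), 3:(w + 2L)]
  sum(core & !(up & dn & lf & rt))
}

# Orientation anisotropy of a pixel set: 1 - sqrt(lambda2 / lambda1) of the
# coordinate covariance. 0 for isotropic blobs and degenerate sets.
.fq_anisotropy <- function(mask) {
  n <- sum(mask)
  if (n < 3L) return(0)
  idx <- which(mask, arr.ind = TRUE)
  cv <- stats::cov(idx)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1L] < 1e-12) return(0)
  1 - sqrt(max(ev[2L], 0) / ev[1L])
}

.fq_skewness <- function(x) {
  if (length(x) < 3L || stats::sd(x) < 1e-12) return(0)
  e1071::skewness(x, type = 2)
}
.fq_kurtosis <- function(x) {
  if (length(x) < 4L || stats::sd(x) < 1e-12) return(0)
  e1071::kurtosis(x, type = 2)
}

# Names of the per-ROI battery; slide-level extended features are the
# tissue-weighted means of these over included ROIs (prefixed "roi_"), plus
# the global block computed in biopsy_features().
.fq_roi_feature_names <- c(
  "collagen_fraction", "od_mean", "od_sd", "od_skewness", "od_kurtosis",
  "entropy_mean", "entropy_sd",
  "glcm_contrast", "glcm_energy", "glcm_homogeneity", "glcm_correlation",
  "collagen_component_count", "collagen_perimeter_density",
  "collagen_anisotropy")

#' Per-ROI feature grids
#'
#' Tiles the slide into non-overlapping `roi_px` x `roi_px` ROIs (edge ROIs
#' may be smaller so the tiling covers the image exactly) and computes the
#' documented per-ROI battery: collagen fraction; OD mean/sd/skewness/
#' kurtosis over tissue pixels; local-entropy mean/sd; co-occurrence
#' contrast, energy, homogeneity and correlation on the quantized OD; and
#' collagen morphology (component count, perimeter density, anisotropy).
#' ROIs with tissue fraction below `roi_min_tissue_fraction` are flagged
#' excluded; slide-level values are tissue-weighted means over included ROIs.
#'
#' @inheritParams local_entropy_map
#' @return A list with `grids` (named list of gr x gc matrices, one per
#'   feature), `tissue_fraction` and `tissue_px` grids, `included` logical
#'   grid, `roi_px`, and `slide` (named vector of tissue-weighted means over
#'   included ROIs, names prefixed `roi_`).
#' @export
compute_roi_features <- function(seg, params = feature_params()) {
  stopifnot(inherits(seg, "collagen_segmentation"))
  h <- nrow(seg$tissue_mask); w <- ncol(seg$tissue_mask)
  roi <- params$roi_px
  gr <- ceiling(h / roi); gc <- ceiling(w / roi)
  H <- local_entropy_map(seg, params)
  rng <- if (any(seg$tissue_mask)) range(seg$sr_od[seg$tissue_mask]) else c(0, 0)
  q <- .fq_quantize(seg$sr_od, params$entropy_bins, rng[1L], rng[2L])

  grids <- lapply(.fq_roi_feature_names,
                  function(nm) matrix(NA_real_, gr, gc))
  names(grids) <- .fq_roi_feature_names
  tf <- matrix(0, gr, gc); tp <- matrix(0L, gr, gc)

  for (gi in seq_len(gr)) {
    r0 <- (gi - 1L) * roi + 1L; r1 <- min(gi * roi, h)
    for (gj in seq_len(gc)) {
      c0 <- (gj - 1L) * roi + 1L; c1 <- min(gj * roi, w)
      t_t <- seg$tissue_mask[r0:r1, c0:c1, drop = FALSE]
      nt <- sum(t_t)
      tf[gi, gj] <- nt / length(t_t); tp[gi, gj] <- nt
      if (nt == 0L) next
      t_c <- seg$collagen_mask[r0:r1, c0:c1, drop = FALSE]
      t_od <- seg$sr_od[r0:r1, c0:c1, drop = FALSE]
      t_H <- H[r0:r1, c0:c1, drop = FALSE]
      odv <- t_od[t_t]; hv <- t_H[t_t]
      g <- .fq_glcm(q[r0:r1, c0:c1, drop = FALSE], t_t, params$entropy_bins)
      grids$collagen_fraction[gi, gj] <- sum(t_c) / nt
      grids$od_mean[gi, gj] <- mean(odv)
      grids$od_sd[gi, gj] <- if (nt > 1L) stats::sd(odv) else 0
      grids$od_skewness[gi, gj] <- .fq_skewness(odv)
      grids$od_kurtosis[gi, gj] <- .fq_kurtosis(odv)
      grids$entropy_mean[gi, gj] <- mean(hv)
      grids$entropy_sd[gi, gj] <- if (nt > 1L) stats::sd(hv) else 0
      grids$glcm_contrast[gi, gj] <- g[["contrast"]]
      grids$glcm_energy[gi, gj] <- g[["energy"]]
      grids$glcm_homogeneity[gi, gj] <- g[["homogeneity"]]
      grids$glcm_correlation[gi, gj] <- g[["correlation"]]
      grids$collagen_component_count[gi, gj] <-
        if (any(t_c)) max(EBImage::bwlabel(t_c * 1)) else 0
      grids$collagen_perimeter_density[gi, gj] <- .fq_perimeter_px(t_c) / nt
      grids$collagen_anisotropy[gi, gj] <- .fq_anisotropy(t_c)
    }
  }

  included <- tf >= params$roi_min_tissue_fraction & tp > 0L
  if (!any(included))
    .fq_stop("all ROIs excluded at roi_min_tissue_fraction=%s",
             params$roi_min_tissue_fraction)
  wts <- tp[included]
  slide <- vapply(grids, function(g) {
    v <- g[included]
    ok <- is.finite(v)
    if (!any(ok)) return(NA_real_)
    stats::weighted.mean(v[ok], wts[ok])
  }, numeric(1))
  names(slide) <- paste0("roi_", names(slide))

  list(grids = grids, tissue_fraction = tf, tissue_px = tp,
       included = included, roi_px = roi, slide = slide)
}

#' Full per-biopsy feature vector
#'
#' Computes the two contractual features — ECA (percent of tissue pixels that
#' are collagen) and EnC (mean local entropy of the SR optical density) — and
#' the extended battery: tissue-weighted per-ROI means from
#' [compute_roi_features()] plus slide-global intensity, entropy, and
#' collagen-morphology measures. The extended battery is a documented,
#' versioned registry (see [feature_registry()]); only ECA and EnC carry
#' contractual semantics.
#'
#' @inheritParams local_entropy_map
#' @param slide_id Identifier copied into the result.
#' @param um_per_px Pixel size used for the area-calibrated features.
#' @return An object of class `biopsy_features`: list with `slide_id`,
#'   `eca_percent`, `enc`, `extended` (named numeric vector), `roi_maps`
#'   (the [compute_roi_features()] result) and `params`.
#' @export
biopsy_features <- function(seg, params = feature_params(),
                            slide_id = "slide", um_per_px = 0.25) {
  eca <- compute_eca(seg)
  enc <- compute_enc(seg, params)
  roi <- compute_roi_features(seg, params)
  H <- local_entropy_map(seg, params)
  tis <- seg$tissue_mask; col <- seg$collagen_mask
  odv <- seg$sr_od[tis]; hv <- H[tis]
  n_comp <- if (any(col)) max(EBImage::bwlabel(col * 1)) else 0
  px_area_um2 <- um_per_px^2
  glob <- c(
    od_mean = mean(odv),
    od_sd = if (sum(tis) > 1L) stats::sd(odv) else 0,
    od_skewness = .fq_skewness(odv),
    od_kurtosis = .fq_kurtosis(odv),
    od_median = stats::median(odv),
    od_p10 = unname(stats::quantile(odv, 0.10)),
    od_p90 = unname(stats::quantile(odv, 0.90)),
    entropy_sd = if (sum(tis) > 1L) stats::sd(hv) else 0,
    entropy_p90 = unname(stats::quantile(hv, 0.90)),
    collagen_od_mean = if (any(col)) mean(seg$sr_od[col]) else NA_real_,
    collagen_od_sd = if (sum(col) > 1L) stats::sd(seg$sr_od[col]) else 0,
    collagen_component_count = n_comp,
    collagen_component_mean_area_um2 =
      if (n_comp > 0) sum(col) * px_area_um2 / n_comp else 0,
    collagen_perimeter_density = .fq_perimeter_px(col) / max(1L, sum(tis)),
    collagen_anisotropy = .fq_anisotropy(col),
    tissue_area_mm2 = sum(tis) * px_area_um2 / 1e6,
    collagen_area_mm2 = sum(col) * px_area_um2 / 1e6
  )
  structure(list(slide_id = as.character(slide_id),
                 eca_percent = eca, enc = enc,
                 extended = c(roi$slide, glob),
                 roi_maps = roi, params = params),
            class = "biopsy_features")
}

#' @export
print.biopsy_features <- function(x, ...) {
  cat(sprintf("biopsy_features '%s': ECA %.2f%%, EnC %.3f, %d extended features\n",
              x$slide_id, x$eca_percent, x$enc, length(x$extended)))
  invisible(x)
}

#' Names and descriptions of the extended feature battery
#'
#' The registry of extended features computed by [biopsy_features()]. ECA and
#' EnC are the two contractual features; the rest form a documented battery
#' of intensity, local-entropy, co-occurrence and collagen-morphology
#' measures at ROI and slide scale.
#'
#' @return A data.frame with columns `feature`, `scale` and `description`.
#' @export
feature_registry <- function() {
  roi_desc <- c(
    collagen_fraction = "fraction of ROI tissue pixels that are collagen",
    od_mean = "mean SR optical density over ROI tissue pixels",
    od_sd = "sd of SR OD over ROI tissue pixels",
    od_skewness = "skewness (type 2) of SR OD over ROI tissue pixels",
    od_kurtosis = "excess kurtosis (type 2) of SR OD over ROI tissue pixels",
    entropy_mean = "mean local OD entropy over ROI tissue pixels",
    entropy_sd = "sd of local OD entropy over ROI tissue pixels",
    glcm_contrast = "co-occurrence contrast of quantized OD",
    glcm_energy = "co-occurrence energy (angular second moment)",
    glcm_homogeneity = "co-occurrence inverse difference moment",
    glcm_correlation = "co-occurrence correlation",
    collagen_component_count = "connected collagen components in the ROI",
    collagen_perimeter_density = "collagen boundary pixels per tissue pixel",
    collagen_anisotropy = "1 - sqrt(eigenvalue ratio) of collagen coordinates")
  glob_desc <- c(
    od_mean = "mean SR OD over tissue", od_sd = "sd of SR OD over tissue",
    od_skewness = "skewness of SR OD over tissue",
    od_kurtosis = "excess kurtosis of SR OD over tissue",
    od_median = "median SR OD over tissue",
    od_p10 = "10th percentile of SR OD", od_p90 = "90th percentile of SR OD",
    entropy_sd = "sd of local entropy over tissue",
    entropy_p90 = "90th percentile of local entropy",
    collagen_od_mean = "mean SR OD over collagen pixels",
    collagen_od_sd = "sd of SR OD over collagen pixels",
    collagen_component_count = "connected collagen components on the slide",
    collagen_component_mean_area_um2 = "mean collagen component area (um^2)",
    collagen_perimeter_density = "collagen boundary pixels per tissue pixel",
    collagen_anisotropy = "global collagen orientation anisotropy",
    tissue_area_mm2 = "tissue section area (mm^2)",
    collagen_area_mm2 = "collagen area (mm^2)")
  rbind(
    data.frame(feature = c("eca_percent", "enc"), scale = "slide",
               description = c(
                 "Estimated Collagen Area: % of tissue pixels that are collagen",
                 "Entropy of Collagen: mean local entropy of SR OD")),
    data.frame(feature = paste0("roi_", names(roi_desc)),
               scale = "roi-mean", description = unname(roi_desc)),
    data.frame(feature = names(glob_desc), scale = "slide",
               description = unname(glob_desc)))
}

# --- Heatmaps ---------------------------------------------------------------

#' Render a per-ROI feature heatmap overlaid on the slide
#'
#' Nearest-neighbour-upsamples a per-ROI feature grid to the image size,
#' color-maps it (viridis), and alpha-blends it over the slide. Excluded ROIs
#' (NA in the grid or FALSE in `included`) are left transparent.
#'
#' @param image A [slide_image()].
#' @param roi_grid Numeric gr x gc matrix of per-ROI values.
#' @param feature_name Label stored in the result.
#' @param alpha Overlay opacity in (0, 1\].
#' @param roi_px ROI side in pixels used to produce the grid (default 32).
#' @param included Optional logical grid; FALSE cells are transparent.
#' @param value_range Optional c(lo, hi) for the color scale; defaults to the
#'   finite range of the grid.
#' @return An object of class `fibro_heatmap`: list with `image` (the blended
#'   h x w x 3 array, 0-255), `overlay_mask`, `feature_name`, `value_range`,
#'   `alpha`, `grid`.
#' @seealso [write_heatmap()]
#' @export
render_heatmap <- function(image, roi_grid, feature_name = "feature",
                           alpha = 0.5, roi_px = 32L, included = NULL,
                           value_range = NULL) {
  stopifnot(inherits(image, "slide_image"), is.matrix(roi_grid))
  if (!(alpha > 0 && alpha <= 1)) .fq_stop("`alpha` must be in (0, 1]")
  h <- dim(image$pixels)[1L]; w <- dim(image$pixels)[2L]
  if (nrow(roi_grid) != ceiling(h / roi_px) ||
      ncol(roi_grid) != ceiling(w / roi_px))
    .fq_stop("grid shape %dx%d does not match the %dx%d image tiled at roi_px=%d",
             nrow(roi_grid), ncol(roi_grid), h, w, roi_px)
  if (!is.null(included)) {
    stopifnot(all(dim(included) == dim(roi_grid)))
    roi_grid[!included] <- NA_real_
  }
  fin <- is.finite(roi_grid)
  if (is.null(value_range)) {
    value_range <- if (any(fin)) range(roi_grid[fin]) else c(0, 1)
  }
  lo <- value_range[1L]; hi <- value_range[2L]
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256L, "viridis")))
  # Map grid cells to palette rows (NA -> 0 = transparent).
  sc <- if (hi - lo < .Machine$double.eps) {
    ifelse(fin, 0.5, NA_real_)
  } else pmin(pmax((roi_grid - lo) / (hi - lo), 0), 1)
  ci <- ifelse(is.na(sc), 0L, pmin(255L, as.integer(floor(sc * 256))) + 1L)
  ri <- pmin(((seq_len(h) - 1L) %/% roi_px) + 1L, nrow(roi_grid))
  cj <- pmin(((seq_len(w) - 1L) %/% roi_px) + 1L, ncol(roi_grid))
  ci_img <- ci[ri, cj, drop = FALSE]
  mask <- ci_img > 0L
  out <- image$pixels
  for (ch in 1:3) {
    colplane <- matrix(0, h, w)
    colplane[mask] <- pal[ci_img[mask], ch]
    plane <- out[, , ch]
    plane[mask] <- (1 - alpha) * plane[mask] + alpha * colplane[mask]
    out[, , ch] <- plane
  }
  structure(list(image = round(out), overlay_mask = mask,
                 feature_name = feature_name,
                 value_range = c(lo, hi), alpha = alpha, grid = roi_grid),
            class = "fibro_heatmap")
}

#' Write a heatmap to PNG
#'
#' @param hm A `fibro_heatmap` from [render_heatmap()] or the response-grid
#'   heatmap from [render_response_heatmap()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(hm, path) {
  img <- if (is.list(hm) && !is.null(hm$image)) hm$image else hm
  png::writePNG(img / 255, path)
  invisible(path)
}
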