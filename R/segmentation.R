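#' Slide image container
#'
#' Wraps an 8-bit RGB pixel array with its digitization metadata. Pixel
#' values are stored 0-255; the array is row-major with origin at the top
#' left (dim = height x width x 3).
#'
#' @param pixels Numeric array h x w x 3 with values in \[0, 255\].
#' @param um_per_px Pixel size in micrometres (> 0); defaults to 0.25, the
#'   pixel size of a 40x objective scan.
#' @param slide_id Identifier string.
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(pixels, um_per_px = 0.25, slide_id = "slide") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L)
    .fq_stop("`pixels` must be an h x w x 3 RGB array")
  if (min(pixels) < 0 || max(pixels) > 255)
    .fq_stop("`pixels` must be 8-bit values in [0, 255]")
  .fq_check_number(um_per_px, "um_per_px", .Machine$double.eps)
  pixels <- array(as.numeric(pixels), dim = dim(pixels))  # drop file metadata
  structure(list(pixels = pixels, um_per_px = um_per_px,
                 slide_id = as.character(slide_id)),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("slide_image '%s': %dx%d px, %.3f um/px\n", x$slide_id,
              dim(x$pixels)[1L], dim(x$pixels)[2L], x$um_per_px))
  invisible(x)
}

#' Convert a synthetic slide to a slide_image
#'
#' @param slide A `synthetic_slide` from [generate_slide()].
#' @param slide_id Identifier; defaults to a seed-derived name.
#' @return A [slide_image()].
#' @export
as_slide_image <- function(slide, slide_id = NULL) {
  stopifnot(inherits(slide, "synthetic_slide"))
  if (is.null(slide_id)) slide_id <- sprintf("synthetic_%d", slide$spec$seed)
  slide_image(slide$image, um_per_px = slide$spec$um_per_px,
              slide_id = slide_id)
}

#' Segmentation parameters
#'
#' Controls tissue detection and collagen segmentation. Tissue is everything
#' that is not near-white background (bright AND unsaturated); collagen is
#' the set of tissue pixels whose optical density, projected onto the
#' Sirius-Red stain vector, exceeds a threshold.
#'
#' @param background_brightness_threshold Pixels with max(R,G,B) above this
#'   (0-255) are background candidates. Default 220.
#' @param background_saturation_threshold Background candidates must also
#'   have HSV saturation below this (0-1). Default 0.08.
#' @param stain_vectors `"auto"` (unit OD vectors fitted to the package's
#'   Sirius-Red / counterstain reference colors) or a 2 x 3 matrix whose rows
#'   are the SR-red and counterstain unit vectors in OD space. Real-slide
#'   vectors should be measured on the scanner at hand and supplied here.
#' @param od_threshold `"otsu"` (threshold chosen by Otsu's method over the
#'   tissue-pixel OD distribution) or an explicit positive number for exact
#'   reproducibility.
#' @param min_object_px Connected components smaller than this are removed
#'   from both masks. Default 10.
#' @param closing_radius_px Radius of the disc used for morphological closing
#'   of the tissue mask. Default 2.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(background_brightness_threshold = 220,
                                background_saturation_threshold = 0.08,
                                stain_vectors = "auto",
                                od_threshold = "otsu",
                                min_object_px = 10L,
                                closing_radius_px = 2L) {
  .fq_check_number(background_brightness_threshold,
                   "background_brightness_threshold", 0, 255)
  .fq_check_number(background_saturation_threshold,
                   "background_saturation_threshold", 0, 1)
  if (is.character(stain_vectors)) {
    if (!identical(stain_vectors, "auto"))
      .fq_stop("`stain_vectors` must be \"auto\" or a 2 x 3 matrix")
  } else {
    if (!is.matrix(stain_vectors) || !all(dim(stain_vectors) == c(2L, 3L)))
      .fq_stop("`stain_vectors` must be \"auto\" or a 2 x 3 matrix")
    nrm <- sqrt(rowSums(stain_vectors^2))
    if (any(nrm < .Machine$double.eps))
      .fq_stop("stain vectors must be nonzero")
    cosang <- sum(stain_vectors[1L, ] * stain_vectors[2L, ]) / prod(nrm)
    if (abs(cosang) > 1 - 1e-6)
      .fq_stop("stain vectors must not be collinear")
  }
  if (is.character(od_threshold)) {
    if (!identical(od_threshold, "otsu"))
      .fq_stop("`od_threshold` must be \"otsu\" or a positive number")
  } else {
    .fq_check_number(od_threshold, "od_threshold", .Machine$double.eps)
  }
  .fq_check_number(min_object_px, "min_object_px", 0, Inf, integer = TRUE)
  .fq_check_number(closing_radius_px, "closing_radius_px", 0, Inf,
                   integer = TRUE)
  structure(list(
    background_brightness_threshold = background_brightness_threshold,
    background_saturation_threshold = background_saturation_threshold,
    stain_vectors = stain_vectors,
    od_threshold = od_threshold,
    min_object_px = as.integer(min_object_px),
    closing_radius_px = as.integer(closing_radius_px)
  ), class = "segmentation_params")
}

# Resolve "auto" stain vectors: unit OD vectors of the reference collagen and
# counterstain colors.
.fq_stain_matrix <- function(params) {
  if (is.matrix(params$stain_vectors)) {
    m <- params$stain_vectors
    return(m / sqrt(rowSums(m^2)))
  }
  od <- function(rgb) -log10(pmax(rgb, 1) / 255)
  m <- rbind(sr = od(.fq_palette$collagen),
             counterstain = od(.fq_palette$parenchyma))
  m / sqrt(rowSums(m^2))
}

#' Per-channel optical density of an RGB image
#'
#' Beer-Lambert transform `OD = -log10(max(I, 1) / 255)` per channel; white
#' maps to 0 and saturated black is capped at a finite value.
#'
#' @param pixels h x w x 3 array of 8-bit values.
#' @return h x w x 3 array of non-negative optical densities.
#' @export
rgb_to_od <- function(pixels) {
  -log10(pmax(pixels, 1) / 255)
}

# Remove connected components smaller than min_px from a logical mask.
.fq_remove_small <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Detect the tissue section in an SR-stained slide
#'
#' Classifies pixels as tissue unless they are near-white scanner background
#' (brightness above and saturation below the configured thresholds), then
#' applies morphological closing with a disc of `closing_radius_px` and
#' removes components smaller than `min_object_px`.
#'
#' @param image A [slide_image()].
#' @param params A [segmentation_params()].
#' @return Logical matrix of the image's height x width; warns (does not
#'   error) if no tissue is found.
#' @export
detect_tissue <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "slide_image"))
  px <- image$pixels
  h <- dim(px)[1L]; w <- dim(px)[2L]
  V <- matrix(pmax(px[, , 1L], px[, , 2L], px[, , 3L]), h, w)
  mn <- matrix(pmin(px[, , 1L], px[, , 2L], px[, , 3L]), h, w)
  S <- (V - mn) / pmax(V, 1)
  tissue <- !(V > params$background_brightness_threshold &
                S < params$background_saturation_threshold)
  if (params$closing_radius_px > 0L && any(tissue) && !all(tissue)) {
    kern <- EBImage::makeBrush(2L * params$closing_radius_px + 1L, "disc")
    tissue <- EBImage::closing(tissue * 1, kern) > 0.5
  }
  tissue <- .fq_remove_small(tissue, params$min_object_px)
  if (!any(tissue))
    warning("no tissue detected: image appears to be entirely background")
  tissue
}

#' Sirius-Red-projected optical density map
#'
#' Projects the per-channel optical density of every pixel onto the SR stain
#' vector (stain separation by OD projection), clipping at zero. Pure white
#' maps to exactly 0; collagen-stained pixels score high.
#'
#' @inheritParams detect_tissue
#' @return Numeric matrix (height x width) of non-negative SR optical
#'   densities.
#' @export
compute_sr_od <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "slide_image"))
  od <- rgb_to_od(image$pixels)
  v <- .fq_stain_matrix(params)[1L, ]
  proj <- od[, , 1L] * v[1L] + od[, , 2L] * v[2L] + od[, , 3L] * v[3L]
  matrix(pmax(proj, 0), dim(od)[1L], dim(od)[2L])
}

#' Collagen segmentation container
#'
#' Bundles the tissue mask, collagen mask, and SR optical-density map for a
#' slide. Normally produced by [segment_collagen()]; the constructor is
#' exported so that feature extraction can be exercised on masks and OD
#' fields constructed directly (e.g. ground truth or unit fixtures).
#'
#' @param tissue_mask,collagen_mask Logical matrices of identical shape;
#'   collagen must be a subset of tissue.
#' @param sr_od Non-negative numeric matrix of the same shape.
#' @param params_used Parameter record echoed into the object.
#' @return An object of class `collagen_segmentation`.
#' @export
collagen_segmentation <- function(tissue_mask, collagen_mask, sr_od,
                                  params_used = NULL) {
  stopifnot(is.logical(tissue_mask), is.logical(collagen_mask),
            is.numeric(sr_od))
  if (!all(dim(tissue_mask) == dim(collagen_mask)) ||
      !all(dim(tissue_mask) == dim(sr_od)))
    .fq_stop("masks and OD map must share dimensions")
  if (any(collagen_mask & !tissue_mask))
    .fq_stop("collagen mask must be contained in the tissue mask")
  if (min(sr_od) < 0)
    .fq_stop("`sr_od` must be non-negative")
  structure(list(tissue_mask = tissue_mask, collagen_mask = collagen_mask,
                 sr_od = sr_od, params_used = params_used),
            class = "collagen_segmentation")
}

#' @export
print.collagen_segmentation <- function(x, ...) {
  nt <- sum(x$tissue_mask)
  cat(sprintf(
    "collagen_segmentation %dx%d | tissue px: %d | collagen px: %d (ECA %.2f%%)\n",
    nrow(x$tissue_mask), ncol(x$tissue_mask), nt, sum(x$collagen_mask),
    if (nt > 0) 100 * sum(x$collagen_mask) / nt else NA_real_))
  invisible(x)
}

# Otsu threshold over a vector of values (between-class variance maximised
# over a 256-level histogram). Operates on masked (tissue-only) samples,
# which EBImage's whole-image otsu cannot do.
.fq_otsu <- function(values, levels = 256L) {
  rng <- range(values)
  if (diff(rng) < .Machine$double.eps) return(rng[2L])
  EBImage::otsu(matrix((values - rng[1L]) / diff(rng), nrow = 1L),
                range = c(0, 1), levels = levels) * diff(rng) + rng[1L]
}

#' Segment Sirius-Red-positive collagen
#'
#' Runs [detect_tissue()] and [compute_sr_od()], then labels as collagen the
#' tissue pixels whose SR-projected OD exceeds the threshold (Otsu over the
#' tissue-pixel OD distribution by default, or an explicit value), and
#' removes collagen components smaller than `min_object_px`.
#'
#' @inheritParams detect_tissue
#' @return A [collagen_segmentation()]; warns and returns an empty collagen
#'   mask when no tissue is present.
#' @examples
#' sl <- generate_slide(synthetic_spec(256, 256, seed = 2, noise_sd = 0))
#' seg <- segment_collagen(as_slide_image(sl))
#' mask_jaccard(seg$collagen_mask, sl$collagen_mask)
#' @export
segment_collagen <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "slide_image"))
  tissue <- suppressWarnings(detect_tissue(image, params))
  od <- compute_sr_od(image, params)
  if (!any(tissue)) {
    warning("empty tissue mask: returning empty collagen segmentation")
    return(collagen_segmentation(tissue, tissue & FALSE, od, params))
  }
  thr <- if (identical(params$od_threshold, "otsu")) {
    .fq_otsu(od[tissue])
  } else params$od_threshold
  collagen <- tissue & od > thr
  collagen <- .fq_remove_small(collagen, params$min_object_px)
  params$od_threshold_used <- thr
  collagen_segmentation(tissue, collagen, od, params)
}
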