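#' Read an RGB slide image from TIFF or PNG
#'
#' Returns 8-bit RGB pixels; grayscale inputs are promoted to RGB with a
#' warning and an alpha channel is dropped. The pixel size is taken from the
#' TIFF resolution tag when present (converted from pixels-per-inch or
#' -centimetre), otherwise it falls back to `default_um_per_px` with a
#' warning (0.25 um, the 40x-scan pixel size).
#'
#' @param path TIFF (.tif/.tiff) or PNG (.png) file.
#' @param slide_id Identifier; defaults to the file name without extension.
#' @param default_um_per_px Fallback pixel size in micrometres.
#' @return A [slide_image()].
#' @export
read_image <- function(path, slide_id = NULL, default_um_per_px = 0.25) {
  if (!file.exists(path)) .fq_stop("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  um <- NA_real_
  if (ext %in% c("tif", "tiff")) {
    arr <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e) .fq_stop("unreadable TIFF %s: %s",
                                                 path, conditionMessage(e)))
    xres <- attr(arr, "x.resolution")
    unit <- attr(arr, "resolution.unit")
    if (!is.null(xres) && is.numeric(xres) && xres > 0) {
      um <- switch(ifelse(is.null(unit), "none", unit),
                   inch = 25400 / xres, cm = 10000 / xres, NA_real_)
    }
  } else if (ext == "png") {
    arr <- tryCatch(png::readPNG(path),
                    error = function(e) .fq_stop("unreadable PNG %s: %s",
                                                 path, conditionMessage(e)))
  } else .fq_stop("unsupported image format: .%s (use TIFF or PNG)", ext)
  if (is.na(um)) {
    warning(sprintf("no pixel-size metadata in %s; assuming %.3g um/px",
                    basename(path), default_um_per_px))
    um <- default_um_per_px
  }
  if (length(dim(arr)) == 2L) {
    warning("grayscale image promoted to RGB")
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  }
  if (dim(arr)[3L] == 4L) arr <- arr[, , 1:3, drop = FALSE]
  if (dim(arr)[3L] != 3L) .fq_stop("image must have 1, 3 or 4 channels")
  if (is.null(slide_id))
    slide_id <- tools::file_path_sans_ext(basename(path))
  slide_image(round(arr * 255), um_per_px = um, slide_id = slide_id)
}

#' Write an RGB slide image to TIFF or PNG
#'
#' @param image A [slide_image()] or an h x w x 3 array of 0-255 values.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  arr <- if (inherits(image, "slide_image")) image$pixels else image
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) tiff::writeTIFF(arr / 255, path,
                                                 bits.per.sample = 8L)
  else if (ext == "png") png::writePNG(arr / 255, path)
  else .fq_stop("unsupported image format: .%s", ext)
  invisible(path)
}

#' Write and read binary masks as PNG
#'
#' Masks are stored as single-channel PNG with values 0/255.
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `write_mask()`: `path` invisibly; `read_mask()`: logical matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  png::readPNG(path) > 0.5
}

#' Write and read an optical-density map as 32-bit float TIFF
#'
#' OD values are stored divided by a fixed cap (3.0, above any attainable
#' 8-bit projected OD) so the file stays in the \[0, 1\] range float TIFF
#' requires; `read_od()` undoes the scaling.
#'
#' @param od Non-negative numeric matrix.
#' @param path TIFF path.
#' @return `write_od()`: `path` invisibly; `read_od()`: numeric matrix.
#' @export
write_od <- function(od, path) {
  tiff::writeTIFF(pmin(od / .fq_od_cap, 1), path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_od
#' @export
read_od <- function(path) {
  tiff::readTIFF(path) * .fq_od_cap
}

#' Pipeline configuration
#'
#' One configuration object drives [run_pipeline()]: the synthetic-cohort
#' block, segmentation and feature parameters, and the master seed. The
#' object round-trips losslessly through JSON ([config_to_json()] /
#' [config_from_json()]), and [config_hash()] gives a digest that changes
#' with any parameter, stamped into every pipeline report for provenance.
#'
#' @param seed Master integer seed.
#' @param synth List: `n`, `stage_profile`, `width_px`, `height_px`,
#'   `disorder`, `noise_sd` for the synthetic cohort (used when no slides
#'   are supplied).
#' @param segmentation A [segmentation_params()].
#' @param features A [feature_params()].
#' @param write_heatmaps Write per-slide ECA/EnC heatmap PNGs.
#' @param response_fixtures Also run the response stage on the packaged
#'   paired-biopsy tables.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            synth = list(n = 3L,
                                         stage_profile = c(0.026, 0.057, 0.109),
                                         width_px = 512L, height_px = 512L,
                                         disorder = 0.3, noise_sd = 2),
                            segmentation = segmentation_params(),
                            features = feature_params(),
                            write_heatmaps = FALSE,
                            response_fixtures = TRUE) {
  .fq_check_number(seed, "seed", -2^31, 2^31, integer = TRUE)
  structure(list(seed = as.integer(seed), synth = synth,
                 segmentation = segmentation, features = features,
                 write_heatmaps = isTRUE(write_heatmaps),
                 response_fixtures = isTRUE(response_fixtures)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
config_to_json <- function(config) {
  jsonlite::toJSON(.fq_strip_classes(config),
                   auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @rdname pipeline_config
#' @param json JSON string or file path produced by [config_to_json()].
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  pipeline_config(
    seed = x$seed,
    synth = x$synth,
    segmentation = do.call(segmentation_params,
                           x$segmentation[setdiff(names(x$segmentation),
                                                  "od_threshold_used")]),
    features = do.call(feature_params, x$features),
    write_heatmaps = x$write_heatmaps,
    response_fixtures = x$response_fixtures)
}

#' @rdname pipeline_config
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(config_to_json(config), f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' Generates (or accepts) a cohort of slides, segments collagen, extracts
#' the feature battery, runs the stage-gradient statistics when the cohort
#' spans more than one stage group, and optionally the paired-response
#' analysis on the packaged fixtures. All outputs are deterministic under a
#' fixed configuration: the feature table (`features.csv`), the stage
#' statistics (`stats.json`), the response report (`response.json`), the
#' response heatmap (`response_heatmap.png`), optional per-slide heatmaps,
#' and a provenance manifest (`provenance.json`) recording the full
#' configuration, its hash (stamped into every JSON report), and the output
#' file hashes.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory to write into (created if needed).
#' @param slides Optional list of `synthetic_slide` or [slide_image()]
#'   objects; when NULL a synthetic cohort is generated from
#'   `config$synth`.
#' @return Invisibly, a list with `features` (data.frame), `stats`,
#'   `response`, `files`, `config_hash`.
#' @export
run_pipeline <- function(config, output_dir, slides = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  files <- character(0)

  if (is.null(slides)) {
    sy <- config$synth
    slides <- generate_cohort(
      n = sy$n, stage_profile = sy$stage_profile, seed = config$seed,
      width_px = sy$width_px, height_px = sy$height_px,
      disorder = sy$disorder, noise_sd = sy$noise_sd)
  }
  imgs <- lapply(seq_along(slides), function(i) {
    s <- slides[[i]]
    if (inherits(s, "synthetic_slide"))
      as_slide_image(s, slide_id = sprintf("slide_%03d", i))
    else s
  })
  stage_group <- vapply(slides, function(s) {
    g <- attr(s, "stage_group"); if (is.null(g)) NA_integer_ else g
  }, integer(1))

  feats <- lapply(imgs, function(im) {
    seg <- segment_collagen(im, config$segmentation)
    bf <- biopsy_features(seg, config$features, slide_id = im$slide_id,
                          um_per_px = im$um_per_px)
    if (config$write_heatmaps) {
      hm <- render_heatmap(im, bf$roi_maps$grids$collagen_fraction,
                           "collagen_fraction", alpha = 0.5,
                           roi_px = config$features$roi_px,
                           included = bf$roi_maps$included)
      write_heatmap(hm, file.path(output_dir,
                                  paste0(im$slide_id, "_eca_heatmap.png")))
    }
    bf
  })
  tab <- do.call(rbind, lapply(feats, function(b)
    data.frame(slide_id = b$slide_id, eca_percent = b$eca_percent,
               enc = b$enc, t(b$extended), check.names = FALSE)))
  tab_path <- file.path(output_dir, "features.csv")
  utils::write.csv(cbind(config_hash = hash, tab), tab_path,
                   row.names = FALSE)
  files <- c(files, tab_path)

  stats_out <- NULL
  gs <- stage_group[!is.na(stage_group)]
  if (length(unique(gs)) >= 2L && all(table(gs) >= 2L) &&
      length(gs) == length(slides)) {
    grp <- factor(paste0("group", stage_group))
    stats_out <- list(
      config_hash = hash,
      anova_tukey_eca = anova_tukey(tab$eca_percent, grp),
      summary_eca = summarize_by_stage(tab$eca_percent, grp),
      summary_enc = summarize_by_stage(tab$enc, grp))
    stats_path <- file.path(output_dir, "stats.json")
    jsonlite::write_json(stats_out, stats_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(files, stats_path)
  }

  resp_out <- NULL
  if (config$response_fixtures) {
    pairs <- load_paired_fixtures("both")
    resp_out <- list(
      config_hash = hash,
      pooled = unclass(summarize_cohort(pairs)),
      study = unclass(summarize_cohort(pairs[pairs$cohort == "study", ])),
      validation = unclass(
        summarize_cohort(pairs[pairs$cohort == "validation", ])))
    resp_path <- file.path(output_dir, "response.json")
    jsonlite::write_json(resp_out, resp_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    hm_path <- file.path(output_dir, "response_heatmap.png")
    render_response_heatmap(pairs, path = hm_path)
    files <- c(files, resp_path, hm_path)
  }

  manifest <- list(config_hash = hash,
                   config = .fq_strip_classes(config),
                   n_slides = length(slides),
                   outputs = stats::setNames(as.list(unname(tools::md5sum(files))),
                                             basename(files)))
  man_path <- file.path(output_dir, "provenance.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(features = tab, stats = stats_out, response = resp_out,
                 files = c(files, man_path), config_hash = hash))
}
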