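#' Read paired pre/post biopsy records from CSV
#'
#' Expected columns: `patient_id, cohort, stage_pre, stage_post,
#' eca_pre_pct, eca_post_pct, enc_pre, enc_post` and optionally
#' `weight_change_pct`. Stage strings are parsed case-insensitively ("1a" is
#' accepted for "F1a"). Validation errors name the offending row.
#'
#' @param path CSV file path.
#' @return data.frame of class `paired_biopsy_records` with parsed ordinal
#'   stage factors.
#' @export
read_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "cohort", "stage_pre", "stage_post",
           "eca_pre_pct", "eca_post_pct", "enc_pre", "enc_post")
  miss <- setdiff(req, names(df))
  if (length(miss))
    .fq_stop("missing column(s) in %s: %s", path, paste(miss, collapse = ", "))
  if (!"weight_change_pct" %in% names(df)) df$weight_change_pct <- NA_real_
  for (i in seq_len(nrow(df))) {
    for (col in c("stage_pre", "stage_post")) {
      ok <- tryCatch({parse_stage(df[[col]][i]); TRUE},
                     error = function(e) FALSE)
      if (!ok) .fq_stop("row %d: unparsable stage '%s' in column %s",
                        i, df[[col]][i], col)
    }
    vals <- unlist(df[i, c("eca_pre_pct", "eca_post_pct",
                           "enc_pre", "enc_post")])
    if (anyNA(vals) || any(vals < 0))
      .fq_stop("row %d: feature values must be present and non-negative", i)
  }
  df$stage_pre <- parse_stage(df$stage_pre)
  df$stage_post <- parse_stage(df$stage_post)
  class(df) <- c("paired_biopsy_records", "data.frame")
  df
}

#' Load the packaged paired-biopsy tables
#'
#' The packaged fixtures transcribe the published pre-/post-treatment tables
#' of the study (9 patients) and validation (8 patients) cohorts: stages,
#' ECA (%) and EnC at their printed precision. Per-patient weight changes
#' were not published; the `weight_change_pct` column is a synthetic
#' stand-in consistent with the published statements (only study patients 2
#' and 6 lost more than 10% of body weight; no validation patient did) and
#' must not be read as measured data.
#'
#' @param cohort `"both"` (default), `"study"`, or `"validation"`.
#' @return A `paired_biopsy_records` data.frame.
#' @export
load_paired_fixtures <- function(cohort = c("both", "study", "validation")) {
  cohort <- match.arg(cohort)
  p <- function(f) system.file("extdata", f, package = "fibroquant",
                               mustWork = TRUE)
  study <- read_pairs(p("table2_study.csv"))
  valid <- read_pairs(p("table3_validation.csv"))
  out <- switch(cohort, study = study, validation = valid,
                both = rbind(study, valid))
  class(out) <- c("paired_biopsy_records", "data.frame")
  out
}

# Ordinal comparison of two stage labels: -1 decrease, 0 none, +1 increase.
.fq_stage_delta_sign <- function(pre, post) {
  sign(match(as.character(parse_stage(post)), stage_levels()) -
         match(as.character(parse_stage(pre)), stage_levels()))
}

#' Classify one paired biopsy: histopathology versus AI
#'
#' The histopathology call is the sign of the ordinal stage change
#' (F1a < F1b < F1c < F2 < F3 < F4). The AI call requires congruous change
#' of both quantitative features at recorded precision: responder when ECA
#' and EnC both strictly decreased, non-responder when both strictly
#' increased, otherwise (discordant or any exactly-zero delta) not
#' conclusive. `congruous_with_histo` is TRUE when the stage changed and
#' both feature deltas share its sign; NA when the stage did not change.
#'
#' @param rec One record: a list or single-row data.frame with fields
#'   `stage_pre, stage_post, eca_pre_pct, eca_post_pct, enc_pre, enc_post`.
#' @return An object of class `response_call`: list with `histo` (one of
#'   `stage_decrease`, `no_change`, `stage_increase`), `ai` (`responder`,
#'   `non_responder`, `not_conclusive`) and `congruous_with_histo`.
#' @export
classify_pair <- function(rec) {
  rec <- as.list(rec)
  s <- .fq_stage_delta_sign(rec$stage_pre, rec$stage_post)
  histo <- c("stage_decrease", "no_change", "stage_increase")[s + 2L]
  d_eca <- rec$eca_post_pct - rec$eca_pre_pct
  d_enc <- rec$enc_post - rec$enc_pre
  ai <- if (d_eca < 0 && d_enc < 0) "responder"
        else if (d_eca > 0 && d_enc > 0) "non_responder"
        else "not_conclusive"
  congr <- if (s == 0L) NA else (sign(d_eca) == s && sign(d_enc) == s)
  structure(list(histo = histo, ai = ai, congruous_with_histo = congr),
            class = "response_call")
}

#' Classify a set of paired biopsies
#'
#' @param records A `paired_biopsy_records` data.frame (e.g. from
#'   [read_pairs()] or [load_paired_fixtures()]).
#' @return data.frame with `patient_id, cohort, histo, ai,
#'   congruous_with_histo` plus the feature deltas.
#' @export
classify_pairs <- function(records) {
  stopifnot(nrow(records) >= 1L)
  calls <- lapply(seq_len(nrow(records)),
                  function(i) classify_pair(records[i, ]))
  data.frame(
    patient_id = records$patient_id, cohort = records$cohort,
    histo = vapply(calls, `[[`, character(1), "histo"),
    ai = vapply(calls, `[[`, character(1), "ai"),
    congruous_with_histo = vapply(calls, function(x)
      if (is.na(x$congruous_with_histo)) NA else x$congruous_with_histo,
      logical(1)),
    d_eca = records$eca_post_pct - records$eca_pre_pct,
    d_enc = records$enc_post - records$enc_pre)
}

#' Weight-loss clinical outcome
#'
#' TRUE when the weight change is strictly more than a 10% loss
#' (`weight_change_percent < -10`); missing weight propagates to NA.
#'
#' @param weight_change_percent Numeric vector of percent weight changes
#'   (negative = loss), or a record with a `weight_change_pct` field.
#' @return Logical vector.
#' @export
weight_outcome <- function(weight_change_percent) {
  if (is.list(weight_change_percent))
    weight_change_percent <- weight_change_percent$weight_change_pct
  weight_change_percent < -10
}

#' Cohort-level response report
#'
#' Aggregates per-pair calls into the descriptive percentages used to
#' compare histopathology with the quantitative (AI) read-out: the
#' histopathology triplet (stage decrease / no change / increase), the AI
#' triplet (responder / non-responder / not conclusive), the AI breakdown
#' within histologically unchanged and changed subsets, the share of pairs
#' with any (nonzero) change of both features, the share with congruous
#' change (responder or non-responder), and the weight-loss outcome lines.
#' Percentages are rounded half-up to integers.
#'
#' @param records A `paired_biopsy_records` data.frame with >= 1 row.
#' @return An object of class `cohort_report` (a list).
#' @examples
#' rep <- summarize_cohort(load_paired_fixtures("study"))
#' rep$histo_change_percent  # 56
#' @export
summarize_cohort <- function(records) {
  if (is.null(nrow(records)) || nrow(records) < 1L)
    .fq_stop("`records` must contain at least one paired biopsy")
  calls <- classify_pairs(records)
  n <- nrow(calls)
  pct <- function(k, d = n) if (d == 0L) NA_real_ else
    round_half_up(100 * k / d)
  histo_n <- c(stage_decrease = sum(calls$histo == "stage_decrease"),
               no_change = sum(calls$histo == "no_change"),
               stage_increase = sum(calls$histo == "stage_increase"))
  ai_n <- c(responder = sum(calls$ai == "responder"),
            non_responder = sum(calls$ai == "non_responder"),
            not_conclusive = sum(calls$ai == "not_conclusive"))
  unch <- calls$histo == "no_change"
  chg <- !unch
  any_change <- calls$d_eca != 0 & calls$d_enc != 0
  congruous_change <- calls$ai != "not_conclusive"
  wo <- weight_outcome(records$weight_change_pct)
  wpos <- which(!is.na(wo) & wo)
  structure(list(
    n_pairs = n,
    histo_counts = histo_n,
    histo_percent = vapply(histo_n, pct, numeric(1)),
    histo_change_percent = pct(sum(chg)),
    ai_counts = ai_n,
    ai_percent = vapply(ai_n, pct, numeric(1)),
    ai_any_change_percent = pct(sum(any_change)),
    ai_congruous_change_percent = pct(sum(congruous_change)),
    pct_ai_decrease_among_histo_unchanged =
      pct(sum(unch & calls$ai == "responder"), sum(unch)),
    pct_ai_increase_among_histo_unchanged =
      pct(sum(unch & calls$ai == "non_responder"), sum(unch)),
    pct_congruous_among_histo_changed =
      pct(sum(chg & !is.na(calls$congruous_with_histo) &
                calls$congruous_with_histo), sum(chg)),
    weight = list(
      n_outcome_positive = length(wpos),
      patient_ids = records$patient_id[wpos],
      ai_responder_share_percent =
        pct(sum(calls$ai[wpos] == "responder"), length(wpos)),
      histo_decrease_share_percent =
        pct(sum(calls$histo[wpos] == "stage_decrease"), length(wpos))),
    calls = calls
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report: %d paired biopsies\n", x$n_pairs))
  cat(sprintf("  histopathology: %d%% decrease / %d%% no change / %d%% increase (change %d%%)\n",
              x$histo_percent[["stage_decrease"]],
              x$histo_percent[["no_change"]],
              x$histo_percent[["stage_increase"]],
              x$histo_change_percent))
  cat(sprintf("  AI: %d%% responder / %d%% non-responder / %d%% not conclusive\n",
              x$ai_percent[["responder"]], x$ai_percent[["non_responder"]],
              x$ai_percent[["not_conclusive"]]))
  cat(sprintf("  AI any-change %d%%, congruous-change %d%%\n",
              x$ai_any_change_percent, x$ai_congruous_change_percent))
  cat(sprintf("  weight outcome (> 10%% loss): %d patient(s)%s\n",
              x$weight$n_outcome_positive,
              if (x$weight$n_outcome_positive)
                paste0(" [", paste(x$weight$patient_ids, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Response heatmap (cases x {histo, ECA, EnC})
#'
#' Renders the per-case classification grid: one row per paired biopsy,
#' three columns. Histopathology column: green = stage decrease, yellow =
#' no change, red = stage increase. ECA and EnC columns: green = value
#' decreased in the post-treatment biopsy, red = increased, yellow =
#' unchanged.
#'
#' @param records A `paired_biopsy_records` data.frame.
#' @param cell_px Side of each grid cell in pixels (default 24).
#' @param path Optional PNG output path.
#' @return List with `grid` (character matrix n x 3 of color names),
#'   `image` (RGB array, 0-255) and `legend` (data.frame mapping colors to
#'   meanings); written to `path` when given.
#' @export
render_response_heatmap <- function(records, cell_px = 24L, path = NULL) {
  calls <- classify_pairs(records)
  n <- nrow(calls)
  col_of_delta <- function(d) ifelse(d < 0, "green", ifelse(d > 0, "red", "yellow"))
  grid <- cbind(
    histo = c(stage_decrease = "green", no_change = "yellow",
              stage_increase = "red")[calls$histo],
    eca = col_of_delta(calls$d_eca),
    enc = col_of_delta(calls$d_enc))
  rownames(grid) <- as.character(calls$patient_id)
  rgb_of <- list(green = c(46, 160, 67), yellow = c(240, 200, 60),
                 red = c(205, 52, 45))
  border <- 2L
  h <- n * cell_px + (n + 1L) * border
  w <- 3L * cell_px + 4L * border
  img <- array(255, dim = c(h, w, 3L))
  for (i in seq_len(n)) for (j in 1:3) {
    r0 <- (i - 1L) * (cell_px + border) + border + 1L
    c0 <- (j - 1L) * (cell_px + border) + border + 1L
    cc <- rgb_of[[grid[i, j]]]
    for (ch in 1:3)
      img[r0:(r0 + cell_px - 1L), c0:(c0 + cell_px - 1L), ch] <- cc[ch]
  }
  legend <- data.frame(
    column = c("histo", "histo", "histo", "eca/enc", "eca/enc", "eca/enc"),
    color = c("green", "yellow", "red", "green", "yellow", "red"),
    meaning = c("stage decrease", "no stage change", "stage increase",
                "value decreased", "value unchanged", "value increased"))
  out <- list(grid = grid, image = img, legend = legend)
  if (!is.null(path)) write_heatmap(out, path)
  out
}
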