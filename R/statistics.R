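#' Fibrosis stage labels
#'
#' The semi-quantitative NASH CRN fibrosis stages used as histopathological
#' ground truth, in their fixed ordinal order: F1a < F1b < F1c < F2 < F3 <
#' F4. The three F1 sub-stages collapse to a coarse F1.
#'
#' @return Character vector of the six fine stage levels, in order.
#' @export
stage_levels <- function() c("F1a", "F1b", "F1c", "F2", "F3", "F4")

#' Parse fibrosis stage labels
#'
#' Case-insensitive; accepts both `"F1a"` and bare `"1a"` forms.
#'
#' @param x Character (or factor) vector of stage labels.
#' @return Ordered factor over [stage_levels()].
#' @export
parse_stage <- function(x) {
  s <- toupper(trimws(as.character(x)))
  s <- sub("^([1-4])", "F\\1", s)
  s <- sub("^F1A$", "F1a", s); s <- sub("^F1B$", "F1b", s)
  s <- sub("^F1C$", "F1c", s)
  bad <- !is.na(s) & !(s %in% stage_levels())
  if (any(bad))
    .fq_stop("unparsable stage label(s): %s",
             paste(unique(x[bad]), collapse = ", "))
  factor(s, levels = stage_levels(), ordered = TRUE)
}

#' Collapse fine stages to coarse F1-F4
#'
#' Maps F1a/F1b/F1c to F1; F2-F4 unchanged.
#'
#' @param x Stage labels (anything [parse_stage()] accepts).
#' @return Ordered factor over F1 < F2 < F3 < F4.
#' @export
coarse_stage <- function(x) {
  s <- as.character(parse_stage(x))
  s[s %in% c("F1a", "F1b", "F1c")] <- "F1"
  factor(s, levels = c("F1", "F2", "F3", "F4"), ordered = TRUE)
}

#' Fleiss' kappa for multi-rater agreement
#'
#' Chance-corrected agreement among `n_raters >= 2` raters each rating every
#' item: `kappa = (P_bar - Pe_bar) / (1 - Pe_bar)`, with `P_bar` the mean
#' over items of the pairwise agreement proportion and `Pe_bar` the sum of
#' squared marginal category proportions.
#'
#' @param ratings Items x raters matrix (or data.frame) of category labels;
#'   no missing values.
#' @param categories Optional category set; defaults to the sorted unique
#'   labels observed. Categories never used still enter with proportion 0.
#' @return Kappa in \[-1, 1\]. When the chance agreement `Pe_bar` is 1 (all
#'   ratings in one category) agreement is necessarily perfect and 1 is
#'   returned.
#' @examples
#' m <- matrix(c("F2","F2","F2", "F3","F3","F3"), nrow = 2, byrow = TRUE)
#' fleiss_kappa(m)  # 1: perfect agreement
#' @export
fleiss_kappa <- function(ratings, categories = NULL) {
  m <- as.matrix(ratings)
  if (nrow(m) < 1L || ncol(m) < 2L)
    .fq_stop("ratings must have >= 1 item and >= 2 raters")
  if (anyNA(m)) .fq_stop("ratings must not contain missing values")
  m[] <- as.character(m)
  if (is.null(categories)) categories <- sort(unique(as.vector(m)))
  if (!all(as.vector(m) %in% categories))
    .fq_stop("ratings contain labels outside `categories`")
  n <- nrow(m); r <- ncol(m)
  counts <- vapply(categories,
                   function(cc) rowSums(m == cc), numeric(n))
  counts <- matrix(counts, nrow = n)  # n x k
  P_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  P_bar <- mean(P_i)
  p_j <- colSums(counts) / (n * r)
  Pe_bar <- sum(p_j^2)
  if (1 - Pe_bar < 1e-12) {
    if (P_bar >= 1 - 1e-12) return(1)
    .fq_stop("kappa undefined: chance agreement is 1 but agreement imperfect")
  }
  (P_bar - Pe_bar) / (1 - Pe_bar)
}

#' Agreement band of a kappa value
#'
#' Maps kappa, rounded to 2 decimals, to the conventional agreement bands:
#' <= 0 "poor/none"; 0.01-0.20 "slight"; 0.21-0.40 "fair"; 0.41-0.60
#' "moderate"; 0.61-0.80 "substantial"; >= 0.81 "almost perfect". Rounding
#' first makes the banding total over \[-1, 1\] with the printed 2-decimal
#' range endpoints.
#'
#' @param kappa Numeric vector in \[-1, 1\].
#' @return Character vector of band labels.
#' @examples
#' kappa_band(c(0.44, 0.73, 0.405))
#' @export
kappa_band <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < -1 - 1e-9) || any(kappa > 1 + 1e-9))
    .fq_stop("kappa must lie in [-1, 1]")
  k2 <- round_half_up(kappa * 100) / 100
  vapply(k2, function(k) {
    if (k <= 0) "poor/none"
    else if (k <= 0.20) "slight"
    else if (k <= 0.40) "fair"
    else if (k <= 0.60) "moderate"
    else if (k <= 0.80) "substantial"
    else "almost perfect"
  }, character(1))
}

#' Read a rating matrix from CSV
#'
#' Rows are biopsies, columns are raters, values are stage labels (anything
#' [parse_stage()] accepts). An optional first column named `item` or
#' `biopsy` is used as row names.
#'
#' @param path CSV file path.
#' @param coarse Collapse F1 sub-stages to F1 before returning.
#' @return Character matrix of validated stage labels.
#' @export
read_ratings <- function(path, coarse = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (tolower(names(df)[1L]) %in% c("item", "biopsy", "case", "id")) {
    rn <- df[[1L]]; df <- df[-1L]
    rownames(df) <- rn
  }
  if (ncol(df) < 2L) .fq_stop("rating CSV needs >= 2 rater columns")
  m <- as.matrix(df)
  parsed <- if (coarse) coarse_stage(as.vector(m)) else parse_stage(as.vector(m))
  matrix(as.character(parsed), nrow(m), ncol(m),
         dimnames = dimnames(m))
}

#' Paired (dependent) t-test
#'
#' Two-sided paired-samples t-test on pre/post measurements, with the
#' significance flag evaluated at p < 0.05.
#'
#' @param pre,post Numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p_value`, `mean_difference` (post - pre)
#'   and `significant`.
#' @export
paired_t_test <- function(pre, post) {
  if (!is.numeric(pre) || !is.numeric(post) || length(pre) != length(post))
    .fq_stop("`pre` and `post` must be numeric vectors of equal length")
  if (length(pre) < 2L) .fq_stop("paired t-test needs n >= 2")
  d <- post - pre
  if (anyNA(d)) .fq_stop("missing values in paired data")
  if (stats::sd(d) < 1e-12)
    .fq_stop("paired t-test undefined: differences have zero variance")
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(d),
       significant = tt$p.value < 0.05)
}

# Significance stars convention used in the stage-gradient figures.
.fq_stars <- function(p) {
  vapply(p, function(x) {
    if (x <= 1e-4) "****" else if (x <= 1e-3) "***"
    else if (x <= 0.01) "**" else if (x <= 0.05) "*" else "ns"
  }, character(1))
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Fits a one-way ANOVA of `values` on `groups` and adjusts all pairwise
#' comparisons with Tukey's honestly-significant-difference (studentized
#' range) procedure.
#'
#' @param values Numeric vector.
#' @param groups Group labels (factor or character); every group must have at
#'   least 2 members, and there must be at least 2 groups.
#' @return List with `anova` (data.frame: F, df_between, df_within, p_value)
#'   and `tukey` (data.frame: comparison, diff, lwr, upr, p_adj, stars).
#' @export
anova_tukey <- function(values, groups) {
  g <- droplevels(factor(groups, ordered = FALSE))
  if (!is.numeric(values) || length(values) != length(g))
    .fq_stop("`values` and `groups` must have equal length")
  if (anyNA(values) || anyNA(g)) .fq_stop("missing values not allowed")
  tab <- table(g)
  if (length(tab) < 2L) .fq_stop("need >= 2 groups")
  if (any(tab < 2L))
    .fq_stop("every group needs >= 2 members (offending: %s)",
             paste(names(tab)[tab < 2L], collapse = ", "))
  fit <- stats::aov(values ~ g)
  sm <- summary(fit)[[1L]]
  an <- data.frame(F = sm[["F value"]][1L],
                   df_between = sm[["Df"]][1L], df_within = sm[["Df"]][2L],
                   p_value = sm[["Pr(>F)"]][1L])
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      stars = .fq_stars(tk[, "p adj"]),
                      row.names = NULL)
  list(anova = an, tukey = tukey)
}

#' Stage-wise summaries
#'
#' Per-group n, mean, sd, SEM, IQR (linear-interpolation quartiles), min and
#' max. Because figure error bars and in-text dispersion statements can mix
#' sd and SEM, both are always reported.
#'
#' @param values Numeric vector.
#' @param groups Group labels of the same length.
#' @return data.frame with one row per group (in factor-level order):
#'   `group, n, mean, sd, sem, iqr, min, max`.
#' @export
summarize_by_stage <- function(values, groups) {
  g <- droplevels(factor(groups))
  if (!is.numeric(values) || length(values) != length(g) || length(g) == 0L)
    .fq_stop("`values` and `groups` must be non-empty and of equal length")
  if (anyNA(values) || anyNA(g)) .fq_stop("missing values not allowed")
  out <- lapply(levels(g), function(lv) {
    v <- values[g == lv]
    n <- length(v)
    s <- if (n > 1L) stats::sd(v) else 0
    data.frame(group = lv, n = n, mean = mean(v), sd = s,
               sem = s / sqrt(n),
               iqr = unname(stats::IQR(v, type = 7)),
               min = min(v), max = max(v))
  })
  do.call(rbind, out)
}
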