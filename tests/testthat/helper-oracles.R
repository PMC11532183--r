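# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately share no code with the package implementation.

# Naive O(N * w^2) mean local entropy: per-pixel window extraction and
# histogram, counting tissue pixels only, bins spanning the tissue OD range.
enc_oracle <- function(od, tissue, window, bins, base = exp(1),
                       support = tissue) {
  h <- nrow(od); w <- ncol(od); r <- (window - 1L) %/% 2L
  rng <- range(od[tissue])
  q <- if (diff(rng) < .Machine$double.eps) {
    matrix(1L, h, w)
  } else {
    qq <- floor((od - rng[1L]) / diff(rng) * bins) + 1
    matrix(pmin(pmax(qq, 1), bins), h, w)
  }
  vals <- numeric(sum(support)); k <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!support[i, j]) next
    rs <- max(1L, i - r):min(h, i + r)
    cs <- max(1L, j - r):min(w, j + r)
    cnt <- tabulate(q[rs, cs][tissue[rs, cs]], nbins = bins)
    p <- cnt[cnt > 0] / sum(cnt)
    k <- k + 1L
    vals[k] <- -sum(p * log(p, base = base))
  }
  mean(vals)
}

# Fleiss kappa by explicit per-item counting of agreeing ordered rater pairs.
fleiss_oracle <- function(m) {
  n <- nrow(m); r <- ncol(m)
  cats <- sort(unique(as.vector(m)))
  agree <- numeric(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (a in seq_len(r)) for (b in seq_len(r))
      if (a != b && m[i, a] == m[i, b]) cnt <- cnt + 1L
    agree[i] <- cnt / (r * (r - 1))
  }
  pj <- vapply(cats, function(cc) sum(m == cc), numeric(1)) / (n * r)
  pe <- sum(pj^2)
  (mean(agree) - pe) / (1 - pe)
}

# IQR by hand: linear-interpolation (type 7) quartiles on the sorted sample.
iqr_oracle <- function(x) {
  s <- sort(x); n <- length(s)
  qat <- function(p) {
    hpos <- (n - 1) * p + 1
    lo <- floor(hpos); hi <- ceiling(hpos)
    s[lo] + (hpos - lo) * (s[hi] - s[lo])
  }
  qat(0.75) - qat(0.25)
}

# A segmentation built directly from arrays (bypasses image segmentation).
make_seg <- function(od, tissue = NULL, collagen = NULL) {
  if (is.null(tissue)) tissue <- matrix(TRUE, nrow(od), ncol(od))
  if (is.null(collagen)) collagen <- matrix(FALSE, nrow(od), ncol(od))
  collagen_segmentation(tissue, collagen, od)
}

# A random tissue/collagen mask pair with collagen inside tissue.
random_masks <- function(h, w, p_tissue = 0.7, p_collagen = 0.15) {
  tissue <- matrix(runif(h * w) < p_tissue, h, w)
  collagen <- tissue & matrix(runif(h * w) < p_collagen, h, w)
  list(tissue = tissue, collagen = collagen)
}
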