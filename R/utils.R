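# Internal helpers shared across modules.

# Reference palette used by the synthetic generator and the default stain
# vectors: near-white scanner background, pale-yellow parenchyma
# (counterstain), saturated Sirius-Red collagen.
.fq_palette <- list(
  background = c(245, 245, 245),
  parenchyma = c(235, 215, 160),
  collagen   = c(170, 30, 40)
)

# Per-channel OD cap; -log10(1/255) ~ 2.41, so 3 bounds any projected value
# comfortably. Used when serializing OD maps to [0,1]-ranged float TIFF.
.fq_od_cap <- 3.0

.fq_stop <- function(...) stop(sprintf(...), call. = FALSE)

.fq_check_number <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .fq_stop("`%s` must be a single finite number", name)
  if (x < lo || x > hi)
    .fq_stop("`%s` must be in [%s, %s], got %s", name, lo, hi, x)
  if (integer && x != round(x))
    .fq_stop("`%s` must be an integer, got %s", name, x)
  invisible(x)
}

# Half-up rounding to integer percent; base round() is round-half-even.
round_half_up <- function(x) floor(x + 0.5)

#' Jaccard index of two binary masks
#'
#' Intersection over union of two logical masks of identical shape. Returns 1
#' when both masks are empty (vacuous agreement).
#'
#' @param a,b Logical matrices of the same dimension.
#' @return A number in \[0, 1\].
#' @export
mask_jaccard <- function(a, b) {
  stopifnot(is.logical(a), is.logical(b), all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

# Sliding-window sums of a numeric matrix over (2r+1)x(2r+1) windows clipped
# at the image border, via a summed-area table. O(h*w) per call.
.fq_box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- apply(m, 2L, cumsum)
  S[-1L, -1L] <- t(apply(S[-1L, -1L, drop = FALSE], 1L, cumsum))
  r1 <- pmax(seq_len(h) - r, 1L); r2 <- pmin(seq_len(h) + r, h)
  c1 <- pmax(seq_len(w) - r, 1L); c2 <- pmin(seq_len(w) + r, w)
  S[r2 + 1L, c2 + 1L, drop = FALSE] -
    S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] +
    S[r1, c1, drop = FALSE]
}

# Quantize a numeric matrix into integer bins 1..bins over [lo, hi],
# clamping out-of-range values into the edge bins. Degenerate range -> bin 1.
.fq_quantize <- function(x, bins, lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || hi - lo < .Machine$double.eps) {
    q <- matrix(1L, nrow(x), ncol(x))
    return(q)
  }
  q <- floor((x - lo) / (hi - lo) * bins) + 1
  q[q < 1] <- 1
  q[q > bins] <- bins
  storage.mode(q) <- "integer"
  q
}

# Recursively strip S3 classes (but keep names) so parameter objects
# serialize as plain JSON maps.
.fq_strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .fq_strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

# Run code with the RNG seeded from `seed`, restoring the caller's RNG state.
.fq_with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

# Deterministic 32-bit-safe child seed from a master seed and an index.
.fq_child_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) * 48271 + 7919 * i) %% 2147483629)
}
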