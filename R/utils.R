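#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# funnel through this so that outputs are pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from a master seed, each below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Bilinear image resampling
#'
#' Resizes a numeric matrix to the requested dimensions with bilinear
#' interpolation (align-corners convention). Used for resolution degradation in
#' the synthetic cohort, the preprocessing resize step, and upsampling of
#' segmentation maps and saliency heatmaps.
#'
#' @param img numeric matrix.
#' @param out_h,out_w target dimensions (positive integers).
#' @return numeric matrix of dimension `out_h x out_w`.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  stopifnot(is.matrix(img), out_h >= 1, out_w >= 1)
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  ri <- if (out_h == 1) rep(1, out_h) else seq(1, h, length.out = out_h)
  ci <- if (out_w == 1) rep(1, out_w) else seq(1, w, length.out = out_w)
  r0 <- pmin(floor(ri), h - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(ci), w - 1L); c0 <- pmax(c0, 1L)
  fr <- ri - r0; fc <- ci - c0
  if (h == 1) { r0 <- rep(1L, out_h); fr <- rep(0, out_h) }
  if (w == 1) { c0 <- rep(1L, out_w); fc <- rep(0, out_w) }
  a <- img[r0, c0, drop = FALSE]; b <- img[pmin(r0 + 1, h), c0, drop = FALSE]
  cc <- img[r0, pmin(c0 + 1, w), drop = FALSE]
  d <- img[pmin(r0 + 1, h), pmin(c0 + 1, w), drop = FALSE]
  fr_m <- matrix(fr, out_h, out_w)
  fc_m <- matrix(fc, out_h, out_w, byrow = TRUE)
  a * (1 - fr_m) * (1 - fc_m) + b * fr_m * (1 - fc_m) +
    cc * (1 - fr_m) * fc_m + d * fr_m * fc_m
}

# Linear operator form of bilinear x2 upsampling, used by the segmentation
# head so the backward pass is the exact transpose of the forward pass.
# Returns list(rows, cols, up) where up(mat_small) -> mat_big and
# down(mat_big_grad) -> mat_small_grad.
upsample2_ops <- function(h_small, w_small) {
  h_big <- 2L * h_small; w_big <- 2L * w_small
  ri <- seq(1, h_small, length.out = h_big)
  ci <- seq(1, w_small, length.out = w_big)
  r0 <- pmax(pmin(floor(ri), h_small - 1L), 1L)
  c0 <- pmax(pmin(floor(ci), w_small - 1L), 1L)
  fr <- ri - r0; fc <- ci - c0
  if (h_small == 1) { r0 <- rep(1L, h_big); fr <- rep(0, h_big) }
  if (w_small == 1) { c0 <- rep(1L, w_big); fc <- rep(0, w_big) }
  r1 <- pmin(r0 + 1L, h_small); c1 <- pmin(c0 + 1L, w_small)
  fr_m <- matrix(fr, h_big, w_big); fc_m <- matrix(fc, h_big, w_big, byrow = TRUE)
  w00 <- (1 - fr_m) * (1 - fc_m); w10 <- fr_m * (1 - fc_m)
  w01 <- (1 - fr_m) * fc_m; w11 <- fr_m * fc_m
  up <- function(m) {
    m[cbind(rep(r0, w_big), rep(c0, each = h_big))] * w00 +
      m[cbind(rep(r1, w_big), rep(c0, each = h_big))] * w10 +
      m[cbind(rep(r0, w_big), rep(c1, each = h_big))] * w01 +
      m[cbind(rep(r1, w_big), rep(c1, each = h_big))] * w11 -> v
    matrix(v, h_big, w_big)
  }
  down <- function(g) {
    out <- matrix(0, h_small, w_small)
    idx00 <- cbind(rep(r0, w_big), rep(c0, each = h_big))
    idx10 <- cbind(rep(r1, w_big), rep(c0, each = h_big))
    idx01 <- cbind(rep(r0, w_big), rep(c1, each = h_big))
    idx11 <- cbind(rep(r1, w_big), rep(c1, each = h_big))
    add_at <- function(out, idx, val) {
      lin <- (idx[, 2] - 1L) * h_small + idx[, 1]
      tab <- rowsum(val, lin)
      out[as.integer(rownames(tab))] <- out[as.integer(rownames(tab))] + tab[, 1]
      out
    }
    out <- add_at(out, idx00, as.vector(g * w00))
    out <- add_at(out, idx10, as.vector(g * w10))
    out <- add_at(out, idx01, as.vector(g * w01))
    add_at(out, idx11, as.vector(g * w11))
  }
  list(up = up, down = down)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically safe log with the package-wide probability clamp.
PROB_EPS <- 1e-7
clamp_prob <- function(p) clamp(p, PROB_EPS, 1 - PROB_EPS)

# Simple FNV-1a hash of a character string, for config provenance headers.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h %% 2^31, b) + (h %/% 2^31) * 2^31
    # 32-bit modular multiply by the FNV prime, split to stay within 2^53
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
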