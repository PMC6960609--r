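# Shared internal helpers: seeded evaluation, clipping, sub-pixel shift
# estimation by cross-correlation.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

clamp01 <- function(x) clamp(x, 0, 1)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Parabolic refinement of a discrete peak: offset in (-0.5, 0.5).
parabolic_offset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (abs(den) < .Machine$double.eps) return(0)
  clamp(0.5 * (ym1 - yp1) / den, -0.5, 0.5)
}

#' Estimate the sub-pixel translation between two images
#'
#' Direct spatial cross-correlation: the interior of `b` (a margin of
#' `max_shift` pixels on every side) is correlated against `a` at every
#' integer displacement up to `max_shift`, and the correlation peak is
#' refined with a separable three-point parabolic fit. Working on true
#' overlapping regions avoids both circular wrap-around and the bias a
#' tapering window would impose on small shifts, so the estimate is
#' accurate for any texture, including very smooth ones.
#'
#' @param a,b numeric matrices of identical dimensions (reference and moved
#'   image), intensities on any common scale.
#' @param max_shift largest displacement searched, in pixels.
#' @return A named numeric vector `c(dx, dy)`: the shift in pixels along the
#'   x (column) and y (row) axes that maps `a` onto `b`. Positive `dx` means
#'   `b` is displaced rightwards.
#' @examples
#' tex <- matrix(sin(outer(1:64, 1:64, function(i, j) 0.3 * i + 0.2 * j)), 64)
#' estimate_shift(tex, tex) # ~ c(0, 0)
#' @export
estimate_shift <- function(a, b, max_shift = 6) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  h <- nrow(a); w <- ncol(a)
  r <- as.integer(max_shift)
  stopifnot(h > 4 * r, w > 4 * r)
  rows <- (r + 1):(h - r); cols <- (r + 1):(w - r)
  bi <- b[rows, cols]
  bi <- bi - mean(bi)
  score <- matrix(NA_real_, 2 * r + 1, 2 * r + 1)
  for (dy in -r:r) {
    for (dx in -r:r) {
      ai <- a[rows - dy, cols - dx]
      ai <- ai - mean(ai)
      score[dy + r + 1, dx + r + 1] <-
        sum(ai * bi) / sqrt(sum(ai^2) * sum(bi^2) + 1e-300)
    }
  }
  peak <- which(score == max(score), arr.ind = TRUE)[1, ]
  py <- unname(peak[1]); px <- unname(peak[2])
  dy <- py - r - 1
  dx <- px - r - 1
  if (py > 1 && py < 2 * r + 1) {
    dy <- dy + parabolic_offset(score[py - 1, px], score[py, px],
                                score[py + 1, px])
  }
  if (px > 1 && px < 2 * r + 1) {
    dx <- dx + parabolic_offset(score[py, px - 1], score[py, px],
                                score[py, px + 1])
  }
  c(dx = dx, dy = dy)
}
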