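# Eulerian video magnification.
#
# Each frame is decomposed into a Laplacian pyramid; at every pyramid level
# the per-pixel time series is band-pass filtered with a zero-phase
# Butterworth filter; the filtered signal is multiplied by the amplification
# factor alpha and added back; the pyramid is collapsed and the result
# clipped to [0, 1]. For small motions this amplifies displacement by
# roughly (1 + alpha) inside the temporal band. The low-pass residual level
# is left untouched so the overall brightness is preserved.

#' Magnification stage parameters
#'
#' @param alpha amplification factor (>= 0). 20 is a good default for
#'   micro-expression clips: strong enough to reveal sub-pixel muscle motion,
#'   below the level where sensor noise dominates.
#' @param f_lo,f_hi temporal pass band in Hz, `0 < f_lo < f_hi < fps/2`.
#'   The default 0.1--0.4 Hz targets slow sub-visible facial motion.
#' @param levels Laplacian pyramid depth (>= 1).
#' @param filter_order Butterworth order (>= 1); applied forward-backward,
#'   so the effective attenuation is doubled and the phase is zero.
#' @param attenuate_chroma if `TRUE`, RGB inputs have their 2nd and 3rd
#'   channels amplified at `alpha / 5` to limit colour artefacts.
#' @return A `magnification_params` list.
#' @export
magnification_params <- function(alpha = 20, f_lo = 0.1, f_hi = 0.4,
                                 levels = 4, filter_order = 1,
                                 attenuate_chroma = FALSE) {
  if (!is_scalar_number(alpha) || alpha < 0) abort("`alpha` must be >= 0")
  if (!(f_lo > 0 && f_hi > f_lo)) abort("need 0 < f_lo < f_hi")
  if (levels < 1) abort("`levels` must be >= 1")
  if (filter_order < 1) abort("`filter_order` must be >= 1")
  structure(list(alpha = alpha, f_lo = f_lo, f_hi = f_hi,
                 levels = as.integer(levels),
                 filter_order = as.integer(filter_order),
                 attenuate_chroma = attenuate_chroma),
            class = "magnification_params")
}

# ---- Laplacian pyramid ------------------------------------------------------

# 5-tap binomial downsample: blur then keep odd rows/cols.
pyr_down <- function(m) {
  b <- blur_binomial5(m)
  b[seq(1, nrow(b), by = 2), seq(1, ncol(b), by = 2), drop = FALSE]
}

# Upsample to an explicit target size: zero-insertion + binomial blur,
# normalised by the blurred sample mask so constants are preserved at the
# borders too (replicated-edge padding otherwise over-weights them).
pyr_up <- function(m, target_dim) {
  H <- target_dim[1]; W <- target_dim[2]
  up <- matrix(0, H, W)
  ones <- matrix(0, H, W)
  up[seq(1, H, by = 2), seq(1, W, by = 2)] <- m
  ones[seq(1, H, by = 2), seq(1, W, by = 2)] <- 1
  blur_binomial5(up) / blur_binomial5(ones)
}

#' Build a Laplacian pyramid of one frame
#'
#' Classical Burt-Adelson construction with the 5-tap binomial kernel:
#' `detail_l = gauss_l - upsample(gauss_{l+1})`, plus a low-pass residual.
#' [collapse_pyramid()] inverts it exactly (to floating-point round-off),
#' because the collapse reuses the identical upsampling operator.
#'
#' @param frame numeric `H x W` matrix.
#' @param levels number of detail levels; the frame's smaller dimension must
#'   be at least `2^levels`.
#' @return List with `details` (list of matrices, full size down to
#'   `ceil(size / 2^(levels-1))`) and `residual` (the low-pass top).
#' @export
build_laplacian_pyramid <- function(frame, levels) {
  if (min(dim(frame)) < 2^levels) {
    abort(sprintf("frame %d x %d is too small for %d pyramid levels",
                  nrow(frame), ncol(frame), levels))
  }
  details <- vector("list", levels)
  g <- frame
  for (l in seq_len(levels)) {
    nxt <- pyr_down(g)
    details[[l]] <- g - pyr_up(nxt, dim(g))
    g <- nxt
  }
  list(details = details, residual = g)
}

#' @rdname build_laplacian_pyramid
#' @param pyr a pyramid as returned by `build_laplacian_pyramid()`.
#' @export
collapse_pyramid <- function(pyr) {
  g <- pyr$residual
  for (l in rev(seq_along(pyr$details))) {
    g <- pyr$details[[l]] + pyr_up(g, dim(pyr$details[[l]]))
  }
  g
}

# ---- temporal filtering -----------------------------------------------------

#' Zero-phase Butterworth band-pass along time
#'
#' Designs a Butterworth band-pass of the given order and applies it
#' forward and backward (squaring the magnitude response, cancelling the
#' phase). Edge transients are tamed by reflect-padding of length
#' `min(3 * order, T - 1)` frames on both ends.
#'
#' @param x numeric vector (one time series), or a `T x P` matrix of `P`
#'   parallel per-pixel series filtered simultaneously.
#' @param fps sampling rate (frames/second).
#' @param f_lo,f_hi pass band in Hz; must satisfy `0 < f_lo < f_hi < fps/2`.
#' @param order Butterworth order.
#' @return Filtered series, same shape as `x`.
#' @export
temporal_bandpass <- function(x, fps, f_lo = 0.1, f_hi = 0.4, order = 1) {
  if (!(f_lo > 0 && f_hi > f_lo && f_hi < fps / 2))
    abort("band must satisfy 0 < f_lo < f_hi < fps/2")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  T_ <- nrow(x)
  if (T_ < 9) abort("need at least 9 frames for temporal filtering")
  bf <- signal::butter(order, c(f_lo, f_hi) / (fps / 2), type = "pass")
  b <- bf$b; a <- bf$a
  # centre each series first: the recursion starts from a zero state, and
  # for narrow bands the state transient decays slowly, so a nonzero mean
  # would bleed a large spurious response into short clips
  mu <- colMeans(x)
  x <- sweep(x, 2, mu)
  npad <- min(3 * order, T_ - 1)
  # reflect padding about the end samples
  top <- 2 * x[rep(1, npad), , drop = FALSE] - x[npad:1 + 1, , drop = FALSE]
  bot <- 2 * x[rep(T_, npad), , drop = FALSE] - x[T_ - (1:npad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  y <- iir_filter_matrix(b, a, xp)
  y <- iir_filter_matrix(b, a, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  out <- y[(npad + 1):(npad + T_), , drop = FALSE]
  if (vec) out[, 1] else out
}

# Direct-form IIR filter applied down the rows of a matrix (vectorised over
# columns).
iir_filter_matrix <- function(b, a, x) {
  n <- nrow(x); p <- ncol(x)
  nb <- length(b); na <- length(a)
  y <- matrix(0, n, p)
  for (t in seq_len(n)) {
    acc <- b[1] * x[t, ]
    if (t > 1) {
      for (k in 2:min(nb, t)) acc <- acc + b[k] * x[t - k + 1, ]
      for (k in 2:min(na, t)) acc <- acc - a[k] * y[t - k + 1, ]
    }
    y[t, ] <- acc / a[1]
  }
  y
}

# ---- magnification ----------------------------------------------------------

#' Magnify sub-visible motion in a sequence
#'
#' @param seq a [frame_sequence()].
#' @param params a [magnification_params()].
#' @return A [frame_sequence()] of the same shape with motion inside the
#'   temporal band amplified; metadata preserved; intensities clipped to
#'   `[0, 1]`.
#' @details When the clip is shorter than one period of `f_lo`
#'   (`T / fps < 1 / f_lo`) the band is below the clip's frequency
#'   resolution; a warning is issued rather than silently proceeding.
#' @export
magnify_sequence <- function(seq, params = magnification_params()) {
  stopifnot(inherits(seq, "frame_sequence"))
  d <- dim(seq$frames)
  T_ <- d[1]
  if (params$f_hi >= seq$fps / 2)
    abort("f_hi must be below the Nyquist frequency fps/2")
  if (T_ / seq$fps < 1 / params$f_lo) {
    warn(sprintf(paste0("clip spans %.3g s but the band starts at %.3g Hz ",
                        "(period %.3g s); the band is below the clip's ",
                        "frequency resolution"),
                 T_ / seq$fps, params$f_lo, 1 / params$f_lo))
  }
  if (params$alpha == 0) return(seq)
  out <- array(0, d)
  for (ch in seq_len(d[4])) {
    alpha_ch <- if (params$attenuate_chroma && ch > 1) params$alpha / 5
                else params$alpha
    # decompose every frame
    pyrs <- lapply(seq_len(T_), function(t)
      build_laplacian_pyramid(seq$frames[t, , , ch], params$levels))
    # band-pass + amplify each detail level across time
    for (l in seq_len(params$levels)) {
      dl <- dim(pyrs[[1]]$details[[l]])
      stack <- matrix(0, T_, prod(dl))
      for (t in seq_len(T_)) stack[t, ] <- as.vector(pyrs[[t]]$details[[l]])
      filt <- temporal_bandpass(stack, seq$fps, params$f_lo, params$f_hi,
                                params$filter_order)
      stack <- stack + alpha_ch * filt
      for (t in seq_len(T_)) pyrs[[t]]$details[[l]] <- matrix(stack[t, ], dl[1], dl[2])
    }
    for (t in seq_len(T_)) out[t, , , ch] <- collapse_pyramid(pyrs[[t]])
  }
  set_frames(seq, clamp01(out))
}
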