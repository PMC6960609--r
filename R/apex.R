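# Apex-frame localisation from frequency-domain amplitude.
#
# The apex is the frame of maximal expression intensity. The detector works
# entirely in the frequency domain: the lowest temporal-frequency components
# of the whole clip (for the default exclusion of 1, the temporal mean) are
# removed by zeroing those planes of the temporal FFT, and each frame is
# then scored by the total 3D-FFT amplitude of a short Hann-tapered
# spatiotemporal window centred on it. Frames that deviate most from the
# clip's temporal baseline carry the largest spectral amplitude, so the
# argmax of the score series is the apex. The taper makes the score respond
# to the window *centre* (an untapered window would give identical spectra
# for any window containing the same frames, since |FFT| is blind to
# circular shifts).

#' Apex detection parameters
#'
#' @param window odd spatiotemporal block length in frames (>= 3). Windows
#'   at the clip ends are clamped (repeat-edge), not zero-padded.
#' @param dc_exclusion number of lowest temporal-frequency planes of the
#'   clip's spectrum removed before scoring (default 1 = the temporal mean).
#' @return An `apex_params` list.
#' @export
apex_params <- function(window = 5, dc_exclusion = 1) {
  window <- as.integer(window)
  if (window < 3 || window %% 2 == 0) abort("`window` must be odd and >= 3")
  if (dc_exclusion < 1) abort("`dc_exclusion` must be >= 1")
  structure(list(window = window, dc_exclusion = as.integer(dc_exclusion)),
            class = "apex_params")
}

#' Per-frame spectral amplitude score
#'
#' @param seq a [frame_sequence()] (RGB input is converted to luminance).
#' @param params an [apex_params()].
#' @return Numeric vector of length `T`: non-negative, finite scores; higher
#'   means more expression energy at that frame.
#' @export
spectral_amplitude_profile <- function(seq, params = apex_params()) {
  stopifnot(inherits(seq, "frame_sequence"))
  d <- dim(seq$frames)
  T_ <- d[1]
  W <- params$window
  if (W > T_) abort(sprintf("window (%d) exceeds sequence length (%d)", W, T_))
  # luminance stack, T x (H*W)
  gray <- matrix(0, T_, d[2] * d[3])
  for (t in seq_len(T_)) gray[t, ] <- as.vector(to_grayscale(get_frame(seq, t)))
  # remove the dc_exclusion lowest temporal-frequency planes of the clip
  Ft <- mvfft(gray)
  freqs <- pmin(0:(T_ - 1), T_ - (0:(T_ - 1)))
  Ft[order(freqs)[seq_len(min(params$dc_exclusion, T_))], ] <- 0
  resid <- array(Re(mvfft(Ft, inverse = TRUE)) / T_, c(T_, d[2], d[3]))
  half <- (W - 1) %/% 2
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(W - 1)) / (W - 1))
  scores <- numeric(T_)
  for (t in seq_len(T_)) {
    idx <- clamp((t - half):(t + half), 1, T_)
    blk <- resid[idx, , , drop = FALSE] * taper
    scores[t] <- sum(Mod(fft(blk)))
  }
  scores
}

#' Locate the apex frame
#'
#' Returns the argmax of [spectral_amplitude_profile()]; scores within a
#' relative 1e-9 of the maximum are treated as tied and the smallest frame
#' index wins.
#'
#' @inheritParams spectral_amplitude_profile
#' @param trust_metadata if `TRUE` and the sequence already carries an apex
#'   index, that value is returned without recomputation.
#' @return Integer frame index (1-based).
#' @export
locate_apex <- function(seq, params = apex_params(), trust_metadata = FALSE) {
  if (trust_metadata && !is.null(seq$apex)) return(seq$apex)
  s <- spectral_amplitude_profile(seq, params)
  tol <- 1e-9 * max(s, .Machine$double.eps)
  which(s >= max(s) - tol)[1]
}
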