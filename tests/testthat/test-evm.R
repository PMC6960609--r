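test_that("the Laplacian pyramid collapses back to the source", {
  set.seed(1)
  I <- matrix(runif(64 * 64), 64, 64)
  p <- build_laplacian_pyramid(I, 4)
  expect_lt(max(abs(collapse_pyramid(p) - I)), 1e-6)
  # constant image: no detail, constant residual
  pc <- build_laplacian_pyramid(matrix(0.4, 32, 32), 3)
  expect_lt(max(abs(unlist(pc$details))), 1e-12)
  expect_equal(max(abs(pc$residual - 0.4)), 0, tolerance = 1e-12)
  # shapes: one full-size detail plus a half-size residual at depth 1
  p1 <- build_laplacian_pyramid(I, 1)
  expect_identical(dim(p1$details[[1]]), c(64L, 64L))
  expect_identical(dim(p1$residual), c(32L, 32L))
  expect_error(build_laplacian_pyramid(matrix(0, 8, 8), 5), "too small")
})

test_that("the zero-phase Butterworth bandpass matches its frequency-response
           oracle", {
  fps <- 30
  tt <- (0:599) / fps
  # oracle: squared magnitude response (forward-backward) of the designed
  # filter, evaluated by polynomial division at the test frequency
  gain_at <- function(f) {
    bf <- signal::butter(1, c(0.1, 0.4) / (fps / 2), type = "pass")
    z <- exp(1i * 2 * pi * f / fps)
    h <- sum(bf$b * z^-(0:2)) / sum(bf$a * z^-(0:2))
    Mod(h)^2
  }
  mid <- 100:500
  y_in <- temporal_bandpass(sin(2 * pi * 0.25 * tt), fps, 0.1, 0.4)
  amp_in <- (max(y_in[mid]) - min(y_in[mid])) / 2
  expect_equal(amp_in, gain_at(0.25), tolerance = 0.02)
  expect_gte(amp_in, 0.9)
  expect_lte(amp_in, 1.0)
  y_out <- temporal_bandpass(sin(2 * pi * 5 * tt), fps, 0.1, 0.4)
  amp_out <- max(abs(y_out[mid]))
  expect_lt(amp_out, 0.05)
  expect_lt(abs(amp_out - gain_at(5)), 0.05)
  # a constant series is rejected entirely
  expect_lt(max(abs(temporal_bandpass(rep(0.7, 60), fps, 0.1, 0.4))), 1e-6)
  expect_error(temporal_bandpass(rnorm(60), fps, 0.1, 20), "Nyquist|band")
  expect_error(temporal_bandpass(rnorm(5), fps, 0.1, 0.4), "9 frames")
})

test_that("magnification amplifies a 0.3 px sinusoid by about (1 + alpha)", {
  sq <- sinusoid_translation_sequence(T = 300, fps = 30, freq = 0.25,
                                      amp_px = 0.3, seed = 2)
  measure <- function(seq) {
    sh <- vapply(seq(20, 280, by = 8), function(t)
      estimate_shift(get_frame(seq, 1), get_frame(seq, t))[["dx"]],
      numeric(1))
    (max(sh) - min(sh)) / 2
  }
  m10 <- measure(magnify_sequence(sq, magnification_params(alpha = 10)))
  expect_gte(m10, 2.4)
  expect_lte(m10, 3.9)
  # monotone growth in alpha
  m5 <- measure(magnify_sequence(sq, magnification_params(alpha = 5)))
  m20 <- measure(magnify_sequence(sq, magnification_params(alpha = 20)))
  expect_true(m5 < m10 && m10 < m20)
})

test_that("zero amplification returns the input unchanged", {
  sq <- sinusoid_translation_sequence(T = 60, fps = 30, seed = 3,
                                      size = c(32, 32))
  out <- suppressWarnings(magnify_sequence(sq, magnification_params(alpha = 0)))
  expect_lt(max(abs(out$frames - sq$frames)), 1e-5)
})

test_that("pixels far from the moving region stay still under magnification", {
  # mouth-only motion (AU12), sub-pixel amplitude; the forehead/brow rows are
  # more than 25 px away from the mouth box
  prof <- motion_profile(3, 9, 15)
  frames <- array(0, c(15, 96, 96, 1))
  for (t in 1:15) {
    frames[t, , , 1] <- render_face(au_activation(12, 0.3), prof(t),
                                    texture_seed = 6)
  }
  sq <- frame_sequence(frames, fps = 30)
  mg <- suppressWarnings(
    magnify_sequence(sq, magnification_params(alpha = 20, f_lo = 0.3,
                                              f_hi = 3, levels = 3)))
  far <- abs(mg$frames[, 1:32, , ] - sq$frames[, 1:32, , ])
  expect_lt(max(far), 0.02)
})

test_that("magnification warns when the band is below the clip's resolution", {
  sq <- sinusoid_translation_sequence(T = 30, fps = 200, size = c(32, 32))
  expect_warning(magnify_sequence(sq, magnification_params(alpha = 2,
                                                           levels = 2)),
                 "below the clip")
})

test_that("magnification preserves shape, fps and metadata", {
  sq <- generate_sequence("happiness", amplitude = 0.5, T = 12, fps = 30,
                          seed = 1, size = c(64, 64))
  mg <- suppressWarnings(magnify_sequence(sq, magnification_params(
    alpha = 5, f_lo = 0.3, f_hi = 3, levels = 3)))
  expect_identical(dim(mg$frames), dim(sq$frames))
  expect_equal(mg$emotion, "happiness")
  expect_equal(mg$apex, sq$apex)
  expect_true(all(mg$frames >= 0 & mg$frames <= 1))
})
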