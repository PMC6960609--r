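test_that("a static clip carries no spectral score and scores have length T", {
  sq <- frame_sequence(array(0.5, c(12, 32, 32, 1)), fps = 30)
  s <- spectral_amplitude_profile(sq)
  expect_length(s, 12)
  expect_true(all(is.finite(s)) && all(s >= 0))
  expect_lt(max(s), 1e-8)
  expect_error(spectral_amplitude_profile(
    frame_sequence(array(0.5, c(3, 8, 8, 1)), fps = 30)), "window")
})

test_that("the spectral argmax recovers a triangular apex and agrees with the
           frame-difference oracle", {
  prof <- motion_profile(5, 17, 30)
  sq <- generate_sequence("surprise", amplitude = 1, T = 35, profile = prof,
                          noise_sd = 0.002, seed = 21)
  det <- locate_apex(sq)
  expect_gte(det, 15)
  expect_lte(det, 19)
  oracle <- which.max(frame_diff_energy(sq))
  expect_lte(abs(det - oracle), 2)
})

test_that("an isolated event is localised exactly and ties break low", {
  sq <- impulse_sequence(22)
  expect_equal(locate_apex(sq), 22)
  two <- impulse_sequence(c(10, 20))
  expect_equal(locate_apex(two), 10)
})

test_that("metadata short-circuits only when trusted", {
  sq <- impulse_sequence(22, T = 30)
  sq$apex <- 7
  expect_equal(locate_apex(sq, trust_metadata = TRUE), 7)
  expect_equal(locate_apex(sq), 22)
})

test_that("shifting the event shifts the detected apex equivariantly", {
  base <- generate_sequence("surprise", amplitude = 1, T = 35,
                            profile = motion_profile(5, 14, 24),
                            noise_sd = 0, seed = 8)
  shifted <- generate_sequence("surprise", amplitude = 1, T = 35,
                               profile = motion_profile(9, 18, 28),
                               noise_sd = 0, seed = 8)
  d <- locate_apex(shifted) - locate_apex(base)
  expect_gte(d, 3)
  expect_lte(d, 5)
})

test_that("moderate pixel noise barely moves the detected apex", {
  prof <- motion_profile(5, 17, 30)
  clean <- generate_sequence("disgust", amplitude = 1, T = 35, profile = prof,
                             noise_sd = 0, seed = 13)
  noisy <- generate_sequence("disgust", amplitude = 1, T = 35, profile = prof,
                             noise_sd = 0.005, seed = 13)
  expect_lte(abs(locate_apex(clean) - locate_apex(noisy)), 2)
})

test_that("apex recovery is accurate over seeded sequences", {
  errs <- vapply(1:12, function(i) {
    apex_true <- 12 + (i %% 9)
    sq <- generate_sequence("surprise", amplitude = 1, T = 35,
                            profile = motion_profile(5, apex_true, 30),
                            noise_sd = 0.002, seed = 100 + i)
    abs(locate_apex(sq) - apex_true)
  }, numeric(1))
  expect_lte(mean(errs), 2)
})
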