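test_that("the renderer is deterministic and neutral at phase zero", {
  f0 <- render_face(NULL, 0, texture_seed = 3)
  expect_identical(f0, render_face(NULL, 0, texture_seed = 3))
  # any activations at phase 0 reproduce the neutral face bit-for-bit
  expect_identical(unclass(render_face(au_activation(c(1, 12, 26), 2), 0,
                                       texture_seed = 3))[],
                   unclass(f0)[])
  f1 <- render_face(au_activation(12, 2), 1, texture_seed = 3)
  expect_identical(f1, render_face(au_activation(12, 2), 1, texture_seed = 3))
  expect_error(render_face(au_activation(99, 1)), "unknown AU")
  expect_error(au_activation(12, -1), "amplitude")
})

test_that("AU12 raises the mouth corners by exactly amplitude * phase", {
  lm0 <- attr(render_face(NULL, 0, texture_seed = 3), "landmarks")
  lm1 <- attr(render_face(au_activation(12, 2), 1, texture_seed = 3),
              "landmarks")
  lm_half <- attr(render_face(au_activation(12, 2), 0.5, texture_seed = 3),
                  "landmarks")
  expect_equal(lm0$mouth_corner_left[2] - lm1$mouth_corner_left[2], 2)
  expect_equal(lm0$mouth_corner_right[2] - lm_half$mouth_corner_right[2], 1)
})

test_that("each AU moves only its own face region", {
  f0 <- render_face(NULL, 0, texture_seed = 5)
  masks <- face_region_masks()
  own_mask <- function(region) {
    switch(region,
           brows = masks$left_brow | masks$right_brow,
           eyes = masks$left_eye | masks$right_eye,
           nose = masks$nose, mouth = masks$mouth)
  }
  for (au in c(1, 2, 4, 5, 6, 7, 9, 10, 12, 15, 17, 20, 25, 26, 43)) {
    fa <- render_face(au_activation(au, 2), 1, texture_seed = 5)
    dif <- abs(fa - f0)
    dif[own_mask(au_region(au))] <- 0
    expect_equal(max(dif), 0, tolerance = 0,
                 label = paste0("AU", au, " leakage outside its region"))
  }
})

test_that("sequences move the emotion's regions and only those", {
  sq <- generate_sequence("surprise", amplitude = 0.8, T = 15, noise_sd = 0,
                          seed = 9)
  # surprise drives AUs 1, 2, 5: brows and eyes; nose and mouth are static
  masks <- face_region_masks(jitter = sq$jitter)
  apex_f <- get_frame(sq, sq$apex)
  onset_f <- get_frame(sq, 1)
  dif <- abs(apex_f - onset_f)
  expect_gt(max(dif[masks$left_brow | masks$right_brow]), 0.01)
  expect_gt(max(dif[masks$left_eye | masks$right_eye]), 0.01)
  # static regions: identical up to the subject-jitter mask approximation
  still <- dif
  still[masks$left_brow | masks$right_brow] <- 0
  still[masks$left_eye | masks$right_eye] <- 0
  expect_equal(max(still), 0, tolerance = 1e-12)
})

test_that("zero amplitude produces a static clip and the apex is where the
           frame-difference oracle says", {
  sq0 <- generate_sequence("sadness", amplitude = 0, T = 10, noise_sd = 0,
                           seed = 2)
  expect_equal(max(abs(sweep(sq0$frames, c(2, 3, 4), sq0$frames[1, , , ]))), 0)
  sq <- generate_sequence("surprise", amplitude = 1, T = 35, noise_sd = 0.002,
                          seed = 5)
  expect_lte(abs(which.max(frame_diff_energy(sq)) - sq$apex), 1)
})

test_that("motion stays sub-pixel for amplitudes below one", {
  amp <- 0.8
  sq <- generate_sequence("happiness", amplitude = amp, T = 9, noise_sd = 0,
                          seed = 4)
  masks <- face_region_masks()
  # measure the mouth-region displacement between onset and apex
  box <- which(masks$mouth, arr.ind = TRUE)
  rows <- range(box[, 1]); cols <- range(box[, 2])
  a <- get_frame(sq, 1)[rows[1]:rows[2], cols[1]:cols[2]]
  b <- get_frame(sq, sq$apex)[rows[1]:rows[2], cols[1]:cols[2]]
  sh <- estimate_shift(a, b)
  expect_lte(sqrt(sum(sh^2)), amp + 0.1)
})

test_that("generate_dataset is balanced, deterministic and multi-subject", {
  emos <- c("happiness", "disgust", "surprise", "happily surprised",
            "disgustedly surprised", "happily disgusted", "sadly angry")
  ds <- generate_dataset(5, sequences_per_subject = 2, emotions = emos,
                         seed = 3, T = 5, size = c(48, 48))
  expect_length(ds$sequences, 70)
  expect_equal(dplyr::n_distinct(ds$manifest$subject_id), 5)
  counts <- table(ds$manifest$class)
  expect_true(all(counts == 10))
  ds2 <- generate_dataset(5, sequences_per_subject = 2, emotions = emos,
                          seed = 3, T = 5, size = c(48, 48))
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$sequences[[1]]$frames, ds2$sequences[[1]]$frames)
  expect_error(generate_dataset(1, emotions = emos), "LOSO")
  expect_error(generate_dataset(3, emotions = character(0)), "empty")
})

test_that("motion profiles hit 0 at the ends and 1 at the apex", {
  for (shape in c("triangular", "gaussian")) {
    p <- motion_profile(5, 17, 30, shape = shape)
    expect_equal(p(5), 0)
    expect_equal(p(17), 1)
    expect_equal(p(30), 0)
    expect_equal(p(c(1, 35)), c(0, 0))
    expect_true(all(diff(p(5:17)) >= 0))
  }
  expect_error(motion_profile(10, 5, 20), "onset <= apex")
})
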