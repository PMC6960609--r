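test_that("frame sequences round-trip losslessly through 8-bit PNG", {
  set.seed(1)
  frames <- array(sample(0:255, 6 * 16 * 12, replace = TRUE) / 255,
                  c(6, 16, 12, 1))
  fs <- frame_sequence(frames, fps = 200, subject_id = "s1",
                       emotion = "surprise", onset = 2, apex = 3, offset = 5)
  dir <- withr::local_tempdir()
  write_sequence(fs, dir)
  back <- read_sequence(dir, metadata = list(fps = 200, subject_id = "s1",
                                             emotion = "surprise",
                                             onset = 2, apex = 3, offset = 5))
  expect_identical(dim(back$frames), dim(fs$frames))
  expect_equal(back$frames, fs$frames, tolerance = 0) # byte-exact
  expect_equal(back$fps, 200)
  expect_equal(back$apex, 3)
  expect_equal(n_frames(back), 6)
})

test_that("read_sequence reports degenerate inputs", {
  dir <- withr::local_tempdir()
  expect_error(read_sequence(dir), "no frames found")
  expect_error(read_sequence(file.path(dir, "nope")), "no such directory")
  png::writePNG(matrix(0.5, 8, 8), file.path(dir, "a.png"))
  png::writePNG(matrix(0.5, 9, 8), file.path(dir, "b.png"))
  expect_error(read_sequence(dir), "inconsistent shape.*b\\.png")
})

test_that("standardize resamples to the target size and preserves metadata", {
  set.seed(2)
  fs <- frame_sequence(array(runif(3 * 60 * 48), c(3, 60, 48, 1)), fps = 60,
                       emotion = "fear", onset = 1, apex = 2, offset = 3)
  out <- standardize(fs, size = c(38, 30))
  expect_identical(dim(out$frames), c(3L, 38L, 30L, 1L))
  expect_equal(out$fps, fs$fps)
  expect_equal(out$emotion, "fear")
  # identity resize is bit-identical
  expect_identical(standardize(fs, size = c(60, 48))$frames, fs$frames)
  # a constant frame stays constant under bilinear resampling
  cf <- frame_sequence(array(0.37, c(2, 40, 40, 1)), fps = 30)
  expect_equal(max(abs(standardize(cf, c(25, 31))$frames - 0.37)), 0,
               tolerance = 1e-12)
  expect_error(standardize(fs, c(0, 10)), "positive")
})

test_that("class_of partitions the 18 emotions into the 7 classes", {
  expect_equal(class_of("disgust"), "Neg")
  expect_equal(class_of("happily surprised"), "PS")
  expect_equal(class_of("sadly angry"), "NN")
  expect_equal(class_of("happiness"), "Pos")
  expect_equal(class_of("surprise"), "Sur")
  expect_equal(class_of("happily disgusted"), "PN")
  expect_equal(class_of("disgustedly surprised"), "NS")
  expect_error(class_of("ennui"), "unknown emotion")

  cls <- class_of(emotion_names())
  expect_length(cls, 18)
  counts <- table(factor(cls, levels = class_names()))
  expect_equal(as.integer(counts),
               c(Pos = 1, Neg = 4, Sur = 1, PS = 1, NS = 4, PN = 1, NN = 6),
               ignore_attr = TRUE)
})

test_that("compound names parse into modifier and head sources", {
  expect_equal(compound_sources("sadly fearful"),
               c(modifier = "sadness", head = "fear"))
  expect_equal(compound_sources("happily surprised"),
               c(modifier = "happiness", head = "surprise"))
  expect_error(compound_sources("sadness"), "not a compound")
})

test_that("manifests round-trip and are validated against class_of", {
  m <- tibble::tibble(subject_id = c("a", "b"),
                      emotion = c("disgust", "happily surprised"),
                      class = c("Neg", "PS"), db = "synthetic",
                      onset = c(3L, 4L), apex = c(10L, 12L),
                      offset = c(20L, 22L), path = c("p1", "p2"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, f)
  back <- read_manifest(f)
  expect_equal(as.data.frame(back), as.data.frame(m))
  m_bad <- m
  m_bad$class <- c("Pos", "PS")
  write_manifest(m_bad, f)
  expect_error(read_manifest(f), "disagrees")
})

test_that("frame_sequence validates its invariants", {
  arr <- array(0.5, c(4, 8, 8))
  expect_error(frame_sequence(arr, fps = 0), "positive")
  expect_error(frame_sequence(arr, fps = 30, onset = 3, apex = 2),
               "onset must not exceed apex")
  expect_error(frame_sequence(arr, fps = 30, apex = 5), "\\[1, T\\]")
  expect_error(frame_sequence(array(0.5, c(2, 4, 4, 2)), fps = 30),
               "channel count")
})
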