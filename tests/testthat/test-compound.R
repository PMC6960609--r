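test_that("the basic AU table holds the six micro-expression profiles", {
  tab <- basic_au_table()
  expect_length(tab, 6)
  expect_equal(tab$happiness$prototypical, c(6L, 12L))
  expect_equal(tab$sadness$prototypical, c(1L, 4L, 15L))
  expect_equal(tab$fear$prototypical, c(1L, 4L, 20L))
  expect_equal(tab$anger$prototypical, c(4L, 7L, 43L))
  expect_equal(tab$disgust$prototypical, c(4L, 7L, 9L, 25L, 26L))
  expect_equal(tab$surprise$prototypical, c(1L, 2L, 5L))
})

test_that("the compound AU table covers all 18 emotions with sane
           proportions", {
  tab <- compound_au_table()
  expect_length(tab, 18)
  expect_setequal(names(tab), emotion_names())
  expect_equal(tab[["happily surprised"]]$prototypical, c(1L, 2L, 12L, 25L))
  expect_equal(tab[["happily surprised"]]$secondary,
               c("5" = 0.64, "26" = 0.67))
  expect_equal(tab$fear$secondary[["5"]], 0.63)
  props <- unlist(lapply(tab, function(p) p$secondary))
  expect_true(all(props > 0 & props <= 1))
  # prototypical and secondary AUs never overlap within a profile
  for (p in tab) {
    expect_length(intersect(p$prototypical, as.integer(names(p$secondary))), 0)
  }
})

test_that("resolve_aus applies the conflict rule and the regional split", {
  hd <- resolve_aus("happily disgusted")
  expect_false(26 %in% hd$resolved_aus) # disgust's jaw drop disappears
  expect_setequal(hd$resolved_aus, c(6, 9, 10, 12, 25))
  expect_equal(hd$source_a, "happiness")
  expect_equal(hd$source_b, "disgust")

  sf <- resolve_aus("sadly fearful")
  expect_equal(sf$region_assignment[["mouth"]], "a")       # sad mouth
  expect_true(all(sf$region_assignment[c("left_eye", "right_eye",
                                         "left_brow", "right_brow",
                                         "nose")] == "b")) # fear upper face
  expect_equal(sf$source_a, "sadness")
  expect_equal(sf$source_b, "fear")

  for (target in setdiff(emotion_names(), basic_emotion_names())) {
    ra <- resolve_aus(target)$region_assignment
    expect_setequal(names(ra), c("left_brow", "right_brow", "left_eye",
                                 "right_eye", "nose", "mouth"))
  }
  expect_error(resolve_aus("sadness"), "not a compound")
})

test_that("the secondary inclusion threshold is honoured", {
  default <- resolve_aus("fearfully surprised")
  expect_true(26 %in% default$resolved_aus)  # 51% >= 0.5
  expect_false(4 %in% default$resolved_aus)  # 47% < 0.5
  loose <- resolve_aus("fearfully surprised", secondary_threshold = 0.4)
  expect_true(4 %in% loose$resolved_aus)
})

test_that("composite_faces blends region-wise with exact copies outside the
           feather band", {
  seed <- 17
  jit <- c(1, 1)
  img_a <- render_face(emotion_activations("happiness", 1.5), 1,
                       texture_seed = seed, jitter = jit)
  img_b <- render_face(emotion_activations("surprise", 1.5), 1,
                       texture_seed = seed, jitter = jit)
  masks <- face_region_masks()
  rec <- resolve_aus("happily surprised")
  out <- composite_faces(img_a, img_b, rec, masks)
  # mouth pixels (eroded by the feather half-width) equal the happiness source
  shrink <- function(mask, r = 4) {
    idx <- which(mask, arr.ind = TRUE)
    rows <- (min(idx[, 1]) + r):(max(idx[, 1]) - r)
    cols <- (min(idx[, 2]) + r):(max(idx[, 2]) - r)
    keep <- matrix(FALSE, nrow(mask), ncol(mask))
    keep[rows, cols] <- mask[rows, cols]
    keep
  }
  mouth_in <- shrink(masks$mouth)
  expect_equal(out[mouth_in], img_a[mouth_in])
  eyes_in <- shrink(masks$left_eye) | shrink(masks$right_eye) |
    shrink(masks$left_brow) | shrink(masks$right_brow)
  expect_equal(out[eyes_in], img_b[eyes_in])
  # background (top rows, far from any mask) comes from img_a
  expect_equal(out[1:10, ], img_a[1:10, ])

  # single-source limit and idempotence
  rec_a <- rec
  rec_a$region_assignment[] <- "a"
  expect_equal(composite_faces(img_a, img_b, rec_a, masks), img_a,
               ignore_attr = TRUE)
  expect_equal(composite_faces(img_a, img_a, rec, masks), img_a,
               ignore_attr = TRUE)
  expect_error(composite_faces(img_a, img_b[1:50, ], rec, masks), "shape")
})

test_that("build_cmed pairs sources within subjects and counts classes", {
  ds <- generate_dataset(2, sequences_per_subject = 1,
                         emotions = c("happiness", "surprise"), seed = 4,
                         T = 7, size = c(96, 96))
  res <- suppressWarnings(build_cmed(ds$sequences, pairing_seed = 1,
                                     targets = c("happily surprised",
                                                 "sadly fearful")))
  expect_equal(nrow(res$samples), 2)           # one PS pair per subject
  expect_true(all(res$samples$emotion == "happily surprised"))
  expect_false(any(res$samples$cross_subject))
  expect_equal(res$class_counts[["PS"]], 2L)
  expect_equal(sum(res$class_counts), 2L)
  expect_equal(res$skipped, c("sadly fearful" = 1L))
  expect_identical(dim(res$samples$apex_img[[1]]), c(96L, 96L))
  # determinism
  res2 <- suppressWarnings(build_cmed(ds$sequences, pairing_seed = 1,
                                      targets = c("happily surprised",
                                                  "sadly fearful")))
  expect_identical(res$samples$subject_id, res2$samples$subject_id)
  expect_identical(res$samples$apex_img[[1]], res2$samples$apex_img[[1]])
  # empty input
  empty <- build_cmed(list())
  expect_equal(nrow(empty$samples), 0)
  expect_true(all(empty$class_counts == 0))
})

test_that("per-database counts are internally consistent with class_of", {
  df <- compound_db_counts()
  expect_equal(nrow(df), 18)
  expect_true(all(df$class == class_of(df$emotion)))
  tot <- cmed_class_totals()
  expect_equal(sum(tot), sum(rowSums(df[, 3:6])))
})
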