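# Compound expression synthesis: resolving the AU set of a compound emotion
# and compositing two basic-expression face images region by region.
#
# A compound emotion inherits AUs from its two source emotions, but not
# their union: only AUs listed in the compound's own profile survive (an AU
# of a source that the compound does not list "automatically disappears" --
# the conflict rule; e.g. the jaw-drop AU26 of disgust is absent from
# happily disgusted, whose mouth is taken over by the lip-corner puller
# AU12 of happiness). Each source then contributes one anatomical half:
# the head (dominant) emotion drives the upper face -- brows, eyes, nose --
# and the modifier emotion drives the mouth, matching the regional
# description of compound generation ("fear eye and sad mouth" for sadly
# fearful, surprised brows with a happy mouth for happily surprised).

#' Resolve the action units and region sources of a compound emotion
#'
#' @param target a compound emotion name (one of the 12 in
#'   [emotion_names()]).
#' @param secondary_threshold minimum usage proportion for a secondary AU of
#'   the compound profile to be included (default 0.5).
#' @return A `compound_recipe` list: `target`, `source_a` (the modifier
#'   emotion), `source_b` (the head emotion), `resolved_aus` (integer AU
#'   codes), and `region_assignment`, a named character vector over the six
#'   face regions with values `"a"` or `"b"`.
#' @examples
#' resolve_aus("happily disgusted")$resolved_aus  # no AU 26
#' resolve_aus("sadly fearful")$region_assignment
#' @export
resolve_aus <- function(target, secondary_threshold = 0.5) {
  target <- tolower(target)
  if (!target %in% compound_emotion_names())
    abort(paste0("'", target, "' is not a compound emotion"))
  src <- compound_sources(target)
  prof <- compound_au_table()[[target]]
  sec <- as.integer(names(prof$secondary)[prof$secondary >= secondary_threshold])
  resolved <- sort(unique(c(prof$prototypical, sec)))
  # conflict rule: source AUs not in the compound's own profile are dropped;
  # resolved is built from the compound profile, so this holds by
  # construction -- recorded here for the record of which source AUs vanish.
  dropped <- sort(setdiff(
    unique(c(basic_au_table()[[src["modifier"]]]$prototypical,
             basic_au_table()[[src["head"]]]$prototypical)),
    c(prof$prototypical, as.integer(names(prof$secondary)))))
  assignment <- c(left_brow = "b", right_brow = "b", left_eye = "b",
                  right_eye = "b", nose = "b", mouth = "a")
  structure(list(target = target,
                 source_a = unname(src["modifier"]),
                 source_b = unname(src["head"]),
                 resolved_aus = resolved,
                 dropped_aus = dropped,
                 region_assignment = assignment),
            class = "compound_recipe")
}

#' @export
print.compound_recipe <- function(x, ...) {
  cat(sprintf("<compound recipe> %s = %s (mouth) + %s (upper face)\n",
              x$target, x$source_a, x$source_b))
  cat("  AUs:", paste(x$resolved_aus, collapse = ", "), "\n")
  if (length(x$dropped_aus) > 0)
    cat("  dropped source AUs:", paste(x$dropped_aus, collapse = ", "), "\n")
  invisible(x)
}

# Separable box blur of odd width w with zero padding, via cumulative sums.
box_blur <- function(m, w) {
  if (w <= 1) return(m)
  r <- (w - 1) %/% 2
  blur1 <- function(x) { # along rows
    n <- nrow(x)
    cs <- rbind(0, apply(x, 2, cumsum))
    hi <- clamp(seq_len(n) + r, 0, n)
    lo <- clamp(seq_len(n) - r - 1, 0, n)
    (cs[hi + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]) / w
  }
  t(blur1(t(blur1(m))))
}

#' Composite two face images region by region
#'
#' Builds the compound image by taking each face region's pixels from the
#' source the recipe assigns it to, blending across a feathering band at
#' region boundaries (separable box filter of width `feather`, so pixels
#' farther than `feather` from any boundary are copied verbatim).
#' Background pixels outside every region mask come from `img_a`.
#'
#' @param img_a,img_b aligned face images (`H x W` matrices or `H x W x 3`
#'   arrays) of identical shape: the modifier and head sources.
#' @param recipe a [resolve_aus()] recipe (fields `region_assignment`).
#' @param region_masks named list of `H x W` logical masks (see
#'   [face_region_masks()]); must cover the six regions and be disjoint up
#'   to the feather band.
#' @param feather blend band width in pixels (odd; default 7).
#' @return Composite image, same shape as the inputs.
#' @export
composite_faces <- function(img_a, img_b, recipe, region_masks,
                            feather = 7) {
  if (!identical(dim(img_a), dim(img_b))) abort("images differ in shape")
  regions <- names(recipe$region_assignment)
  miss <- setdiff(regions, names(region_masks))
  if (length(miss) > 0)
    abort(paste0("region_masks is missing: ", paste(miss, collapse = ", ")))
  d <- dim(region_masks[[1]])
  overlap <- Reduce(`+`, lapply(region_masks[regions], function(m) m * 1))
  if (sum(overlap > 1) > feather * max(d)) {
    abort("region masks overlap by more than the feather band")
  }
  wb <- matrix(0, d[1], d[2])
  for (rg in regions) {
    if (recipe$region_assignment[[rg]] == "b") {
      wb[region_masks[[rg]]] <- 1
    }
  }
  w <- box_blur(wb, feather)
  # blend only where the b-weight is active; elsewhere exact copy of a
  blend <- function(a, b) (1 - w) * a + w * b
  if (length(dim(img_a)) == 2L) {
    blend(img_a, img_b)
  } else {
    out <- img_a
    for (ch in seq_len(dim(img_a)[3])) {
      out[, , ch] <- blend(img_a[, , ch], img_b[, , ch])
    }
    out
  }
}

#' Build a compound micro-expression dataset from basic-emotion samples
#'
#' For each of the 12 compound emotions whose two source emotions are both
#' present among `samples`, pairs of source sequences are drawn -- within
#' the same subject when possible, across subjects otherwise (flagged) --
#' and their onset, apex and offset frames are composited with
#' [composite_faces()]. Compounds lacking a source are skipped with a
#' warning count.
#'
#' @param samples list of [frame_sequence()] objects carrying basic emotion
#'   labels and onset/apex/offset metadata (e.g. from [generate_dataset()]).
#' @param pairing_seed integer seed making the pairing deterministic.
#' @param region_masks masks passed to [composite_faces()]; default the
#'   neutral-geometry masks for the frame size.
#' @param targets compound emotions to build (default all 12).
#' @param feather blend band width.
#' @return List with `samples`: a tibble (`emotion, class, subject_id,
#'   cross_subject`, and list-columns `onset_img, apex_img, offset_img`),
#'   `class_counts`: named count vector over the 7 classes, and `skipped`:
#'   named count of compounds skipped for lack of sources.
#' @export
build_cmed <- function(samples, pairing_seed = 1, region_masks = NULL,
                       targets = compound_emotion_names(), feather = 7) {
  if (length(samples) == 0) {
    return(list(samples = tibble(emotion = character(), class = character(),
                                 subject_id = character(),
                                 cross_subject = logical(),
                                 onset_img = list(), apex_img = list(),
                                 offset_img = list()),
                class_counts = setNames(integer(7), class_names()),
                skipped = setNames(integer(0), character(0))))
  }
  emo <- vapply(samples, function(s) s$emotion %||% NA_character_, character(1))
  subj <- vapply(samples, function(s) s$subject_id %||% NA_character_, character(1))
  if (anyNA(emo)) abort("every sample needs an emotion label")
  if (is.null(region_masks)) {
    d <- dim(samples[[1]]$frames)
    region_masks <- face_region_masks(c(d[2], d[3]))
  }
  key_frames <- function(s) {
    T_ <- n_frames(s)
    c(s$onset %||% 1, s$apex %||% ((T_ + 1) %/% 2), s$offset %||% T_)
  }
  rows <- list()
  skipped <- integer(0)
  for (target in targets) {
    rec <- resolve_aus(target)
    ia_all <- which(emo == rec$source_a)
    ib_all <- which(emo == rec$source_b)
    if (length(ia_all) == 0 || length(ib_all) == 0) {
      warn(paste0("no source pair available for '", target, "'; skipped"))
      skipped[target] <- 1L
      next
    }
    pairs <- with_preserved_seed(pairing_seed + match(target, targets), {
      ia <- ia_all[sample.int(length(ia_all))]
      ib <- ib_all[sample.int(length(ib_all))]
      # same-subject pairs first
      out <- list()
      used_b <- logical(length(ib))
      for (i in ia) {
        j <- which(!used_b & subj[ib] == subj[i])
        if (length(j) > 0) { out[[length(out) + 1]] <- c(i, ib[j[1]]); used_b[j[1]] <- TRUE }
      }
      matched_a <- vapply(out, `[`, 0L, 1)
      rest_a <- setdiff(ia, matched_a)
      rest_b <- ib[!used_b]
      for (k in seq_len(min(length(rest_a), length(rest_b)))) {
        out[[length(out) + 1]] <- c(rest_a[k], rest_b[k])
      }
      out
    })
    for (p in pairs) {
      sa <- samples[[p[1]]]; sb <- samples[[p[2]]]
      ka <- key_frames(sa); kb <- key_frames(sb)
      imgs <- lapply(1:3, function(i) {
        composite_faces(get_frame(sa, ka[i]), get_frame(sb, kb[i]),
                        rec, region_masks, feather = feather)
      })
      rows[[length(rows) + 1]] <- tibble(
        emotion = target, class = class_of(target),
        subject_id = if (sa$subject_id == sb$subject_id) sa$subject_id
                     else paste0(sa$subject_id, "+", sb$subject_id),
        cross_subject = sa$subject_id != sb$subject_id,
        onset_img = list(imgs[[1]]), apex_img = list(imgs[[2]]),
        offset_img = list(imgs[[3]]))
    }
  }
  df <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble(emotion = character(), class = character(),
           subject_id = character(), cross_subject = logical(),
           onset_img = list(), apex_img = list(), offset_img = list())
  counts <- setNames(integer(7), class_names())
  if (nrow(df) > 0) {
    tab <- table(factor(df$class, levels = class_names()))
    counts <- setNames(as.integer(tab), class_names())
  }
  list(samples = df, class_counts = counts, skipped = skipped)
}
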