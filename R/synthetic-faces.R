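# Procedural face-video generator with FACS action-unit parameterised
# sub-pixel motion.
#
# The renderer draws a schematic face (elliptical head with seeded skin
# texture, two brows, two eyes, nose, mouth) from a continuous parametric
# geometry, so displacing a feature by a fraction of a pixel produces a
# smooth intensity change -- exactly the sub-visible motion regime the
# pipeline is built for. Each supported action unit (AU) displaces or
# deforms one facial region along a documented axis; an emotion's AU set
# therefore moves only its own regions, which makes per-region motion
# testable against the generator's own bookkeeping.
#
# Every feature's ink has compact support (hard cutoff at ~4 sigma), so in
# noise-free mode regions untouched by the active AUs are *bit-identical*
# across frames.

# AU codes appearing in the basic/compound AU tables.
.supported_aus <- c(1, 2, 4, 5, 6, 7, 9, 10, 11, 12, 15, 17, 20, 23, 24, 25, 26, 43)

.au_regions <- c(
  "1" = "brows", "2" = "brows", "4" = "brows",
  "5" = "eyes", "6" = "eyes", "7" = "eyes", "43" = "eyes",
  "9" = "nose",
  "10" = "mouth", "11" = "mouth", "12" = "mouth", "15" = "mouth",
  "17" = "mouth", "20" = "mouth", "23" = "mouth", "24" = "mouth",
  "25" = "mouth", "26" = "mouth"
)

#' Face region affected by an action unit
#'
#' @param au integer AU code(s).
#' @return Character vector: `"brows"`, `"eyes"`, `"nose"` or `"mouth"`.
#' @export
au_region <- function(au) {
  bad <- setdiff(au, .supported_aus)
  if (length(bad) > 0)
    abort(paste0("unknown AU code(s): ", paste(bad, collapse = ", ")))
  unname(.au_regions[as.character(au)])
}

#' Build a set of action-unit activations
#'
#' @param au integer vector of AU codes.
#' @param amplitude peak displacement in pixels (recycled); typical
#'   micro-expression amplitudes are 0.1--2 px.
#' @return Tibble with columns `au`, `amplitude`, `region`.
#' @export
au_activation <- function(au, amplitude = 1) {
  region <- au_region(au)
  if (any(!is.finite(amplitude)) || any(amplitude < 0))
    abort("`amplitude` must be finite and >= 0")
  tibble(au = as.integer(au),
         amplitude = rep_len(as.numeric(amplitude), length(au)),
         region = region)
}

# ---- geometry ---------------------------------------------------------------

# Neutral face geometry in pixel units for an H x W canvas. `jitter` is a
# length-2 multiplier (x, y) encoding subject identity (~ +/- 3%).
face_geometry <- function(size, jitter = c(1, 1)) {
  H <- size[1]; W <- size[2]
  jx <- jitter[1]; jy <- jitter[2]
  cx <- W / 2
  cy <- 0.52 * H
  list(
    H = H, W = W, cx = cx, cy = cy,
    head_rx = 0.42 * W, head_ry = 0.44 * H, head_cy = cy + 0.02 * H,
    brow_y = cy - 0.26 * H * jy,
    brow_inner_dx = 0.08 * W * jx, brow_outer_dx = 0.30 * W * jx,
    brow_sigma = 1.2, brow_ink = 0.55,
    eye_y = cy - 0.08 * H * jy, eye_dx = 0.21 * W * jx,
    eye_rx = 0.07 * W * jx, eye_ry = 0.032 * H * jy, eye_ink = 0.6,
    nose_top_y = cy - 0.04 * H * jy, nose_bot_y = cy + 0.06 * H * jy,
    nostril_dx = 3.5 * jx, nose_sigma = 1.5, nostril_sigma = 1.0,
    nose_ink = 0.3, nostril_ink = 0.45,
    mouth_y = cy + 0.25 * H * jy, mouth_hw = 0.16 * W * jx,
    mouth_gap = 1.2, lip_sigma = 1.2, lip_ink = 0.55,
    arch_up = 1.5, arch_lo = 1.0
  )
}

# Neutral parameter set deformed by AU activations at a given phase.
# Displacement rules (amplitude a in px, phase-scaled):
#   AU1 inner brow up; AU2 outer brow up; AU4 brow down + inward knit;
#   AU5 aperture widens; AU6/7 lids tighten (aperture narrows); AU43 closes;
#   AU9 nose shortens (top moves down); AU10/11 upper lip up;
#   AU12 corners up + slight widen; AU15 corners down; AU17 lower lip up;
#   AU20 horizontal stretch; AU23 tighten (narrow); AU24 press (gap close);
#   AU25 lips part; AU26 jaw drop (gap + lower lip down).
apply_activations <- function(geom, activations, phase) {
  p <- list(
    brow_inner_dy = 0, brow_outer_dy = 0, brow_inner_dx = 0,
    eye_ry_d = 0, nose_top_dy = 0,
    corner_dy = 0, hw_d = 0, gap_d = 0, up_shift = 0, lo_shift = 0
  )
  if (!is.null(activations) && nrow(activations) > 0) {
    for (i in seq_len(nrow(activations))) {
      a <- activations$amplitude[i] * phase
      switch(as.character(activations$au[i]),
        "1"  = { p$brow_inner_dy <- p$brow_inner_dy - a },
        "2"  = { p$brow_outer_dy <- p$brow_outer_dy - a },
        "4"  = { p$brow_inner_dy <- p$brow_inner_dy + a
                 p$brow_outer_dy <- p$brow_outer_dy + 0.5 * a
                 p$brow_inner_dx <- p$brow_inner_dx + 0.5 * a },
        "5"  = { p$eye_ry_d <- p$eye_ry_d + a },
        "6"  = { p$eye_ry_d <- p$eye_ry_d - 0.4 * a },
        "7"  = { p$eye_ry_d <- p$eye_ry_d - 0.6 * a },
        "43" = { p$eye_ry_d <- p$eye_ry_d - a },
        "9"  = { p$nose_top_dy <- p$nose_top_dy + a },
        "10" = { p$up_shift <- p$up_shift - a },
        "11" = { p$up_shift <- p$up_shift - 0.3 * a },
        "12" = { p$corner_dy <- p$corner_dy - a; p$hw_d <- p$hw_d + 0.3 * a },
        "15" = { p$corner_dy <- p$corner_dy + a },
        "17" = { p$lo_shift <- p$lo_shift - a },
        "20" = { p$hw_d <- p$hw_d + a },
        "23" = { p$hw_d <- p$hw_d - 0.5 * a },
        "24" = { p$gap_d <- p$gap_d - 0.5 * a },
        "25" = { p$gap_d <- p$gap_d + a },
        "26" = { p$gap_d <- p$gap_d + a; p$lo_shift <- p$lo_shift + 0.5 * a },
        abort(paste0("unknown AU code: ", activations$au[i]))
      )
    }
  }
  p
}

# ---- drawing primitives (compact support) -----------------------------------

# Gaussian ink along a line segment, zero beyond 4 sigma.
segment_ink <- function(X, Y, x0, y0, x1, y1, sigma, strength) {
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx^2 + vy^2
  tt <- if (L2 < 1e-12) 0 else clamp(((X - x0) * vx + (Y - y0) * vy) / L2, 0, 1)
  dx <- X - (x0 + tt * vx); dy <- Y - (y0 + tt * vy)
  d2 <- dx^2 + dy^2
  ink <- strength * exp(-d2 / sigma^2)
  ink[d2 > (4 * sigma)^2] <- 0
  ink
}

polyline_ink <- function(X, Y, px, py, sigma, strength) {
  n <- length(px)
  d2min <- NULL
  for (i in seq_len(n - 1)) {
    vx <- px[i + 1] - px[i]; vy <- py[i + 1] - py[i]
    L2 <- vx^2 + vy^2
    tt <- if (L2 < 1e-12) 0 else clamp(((X - px[i]) * vx + (Y - py[i]) * vy) / L2, 0, 1)
    dx <- X - (px[i] + tt * vx); dy <- Y - (py[i] + tt * vy)
    d2 <- dx^2 + dy^2
    d2min <- if (is.null(d2min)) d2 else pmin(d2min, d2)
  }
  ink <- strength * exp(-d2min / sigma^2)
  ink[d2min > (4 * sigma)^2] <- 0
  ink
}

# Soft ellipse: ink = k * exp(-g^2) with g = (dx/rx)^2 + (dy/ry)^2, cut at g > 2.5.
ellipse_ink <- function(X, Y, cx, cy, rx, ry, strength) {
  g <- ((X - cx) / rx)^2 + ((Y - cy) / ry)^2
  ink <- strength * exp(-g^2)
  ink[g > 2.5] <- 0
  ink
}

# ---- renderer ---------------------------------------------------------------

#' Render one synthetic face frame
#'
#' Draws the schematic face deformed by `activations` scaled by `phase`.
#' The output is deterministic in all arguments; `phase = 0` reproduces the
#' neutral face bit-for-bit regardless of the activations. The returned
#' matrix carries a `landmarks` attribute (named list of `c(x, y)` points:
#' brow inner/outer ends, eye centres, nose tip, mouth corners) maintained by
#' the same parametric geometry that drives the drawing, so displacement
#' rules can be verified against it.
#'
#' @param activations tibble from [au_activation()], or `NULL` for neutral.
#' @param phase motion phase in `[0, 1]`; feature displacement is
#'   `amplitude * phase` pixels.
#' @param size `c(H, W)` canvas in pixels.
#' @param texture_seed integer seed for the skin texture.
#' @param jitter length-2 multiplier `c(x, y)` for subject geometry identity.
#' @return `H x W` matrix in `[0, 1]` with attribute `landmarks`.
#' @export
render_face <- function(activations = NULL, phase = 0, size = c(96, 96),
                        texture_seed = 1, jitter = c(1, 1)) {
  if (!is_scalar_number(phase) || phase < 0 || phase > 1)
    abort("`phase` must be a number in [0, 1]")
  if (any(size <= 0)) abort("`size` must be positive")
  H <- as.integer(size[1]); W <- as.integer(size[2])
  g <- face_geometry(c(H, W), jitter)
  p <- apply_activations(g, activations, phase)

  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), times = W), H, W)

  # skin: seeded smooth texture on the head ellipse, flat background outside
  tex <- with_preserved_seed(texture_seed, {
    n <- matrix(rnorm(H * W), H, W)
    for (i in 1:3) n <- blur_binomial5(n)
    n / max(abs(n))
  })
  head_g <- ((X - g$cx) / g$head_rx)^2 + ((Y - g$head_cy) / g$head_ry)^2
  inside <- 1 / (1 + exp((head_g - 1) * 12))   # soft edge ~1 px
  skin <- 0.78 + 0.08 * tex
  img <- 0.12 + (skin - 0.12) * inside

  ink <- matrix(0, H, W)
  # brows: inner end toward midline, outer end lateral
  bi_l <- c(g$cx - g$brow_inner_dx + p$brow_inner_dx, g$brow_y + p$brow_inner_dy)
  bo_l <- c(g$cx - g$brow_outer_dx, g$brow_y + 1 + p$brow_outer_dy)
  bi_r <- c(g$cx + g$brow_inner_dx - p$brow_inner_dx, g$brow_y + p$brow_inner_dy)
  bo_r <- c(g$cx + g$brow_outer_dx, g$brow_y + 1 + p$brow_outer_dy)
  ink <- ink + segment_ink(X, Y, bi_l[1], bi_l[2], bo_l[1], bo_l[2],
                           g$brow_sigma, g$brow_ink)
  ink <- ink + segment_ink(X, Y, bi_r[1], bi_r[2], bo_r[1], bo_r[2],
                           g$brow_sigma, g$brow_ink)
  # eyes: aperture (vertical semi-axis) responds to lid AUs
  ery <- max(g$eye_ry + p$eye_ry_d, 0.6)
  ex_l <- g$cx - g$eye_dx; ex_r <- g$cx + g$eye_dx
  ink <- ink + ellipse_ink(X, Y, ex_l, g$eye_y, g$eye_rx, ery, g$eye_ink)
  ink <- ink + ellipse_ink(X, Y, ex_r, g$eye_y, g$eye_rx, ery, g$eye_ink)
  # nose: bridge segment + nostrils; AU9 shortens from the top
  ntop <- g$nose_top_y + p$nose_top_dy
  ink <- ink + segment_ink(X, Y, g$cx, ntop, g$cx, g$nose_bot_y,
                           g$nose_sigma, g$nose_ink)
  ink <- ink + ellipse_ink(X, Y, g$cx - g$nostril_dx, g$nose_bot_y,
                           g$nostril_sigma, g$nostril_sigma, g$nostril_ink)
  ink <- ink + ellipse_ink(X, Y, g$cx + g$nostril_dx, g$nose_bot_y,
                           g$nostril_sigma, g$nostril_sigma, g$nostril_ink)
  # mouth: two lip polylines; corners shared, vertical offset quadratic
  hw <- max(g$mouth_hw + p$hw_d, 3)
  gap <- max(g$mouth_gap + p$gap_d, 0)
  xs <- seq(-1, 1, length.out = 17)
  mx <- g$cx + xs * hw
  cshape <- p$corner_dy * xs^2
  y_up <- g$mouth_y - gap / 2 - g$arch_up * (1 - xs^2) + cshape + p$up_shift
  y_lo <- g$mouth_y + gap / 2 + g$arch_lo * (1 - xs^2) + cshape + p$lo_shift
  ink <- ink + polyline_ink(X, Y, mx, y_up, g$lip_sigma, g$lip_ink)
  ink <- ink + polyline_ink(X, Y, mx, y_lo, g$lip_sigma, g$lip_ink)

  out <- clamp01(img - ink)
  attr(out, "landmarks") <- list(
    left_brow_inner = bi_l, left_brow_outer = bo_l,
    right_brow_inner = bi_r, right_brow_outer = bo_r,
    left_eye = c(ex_l, g$eye_y), right_eye = c(ex_r, g$eye_y),
    eye_aperture = ery,
    nose_top = c(g$cx, ntop),
    mouth_corner_left = c(g$cx - hw, g$mouth_y + p$corner_dy),
    mouth_corner_right = c(g$cx + hw, g$mouth_y + p$corner_dy)
  )
  out
}

# 5-tap binomial blur [1 4 6 4 1]/16, separable, replicated edges.
blur_binomial5 <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  pad_idx <- function(n) c(1, 1, seq_len(n), n, n)
  conv1 <- function(x) {   # along rows (columns of matrix stay)
    n <- nrow(x)
    xp <- x[pad_idx(n), , drop = FALSE]
    k[1] * xp[1:n, , drop = FALSE] + k[2] * xp[2:(n + 1), , drop = FALSE] +
      k[3] * xp[3:(n + 2), , drop = FALSE] + k[4] * xp[4:(n + 3), , drop = FALSE] +
      k[5] * xp[5:(n + 4), , drop = FALSE]
  }
  t(conv1(t(conv1(m))))
}

# ---- region masks -----------------------------------------------------------

#' Binary masks for the six facial regions
#'
#' Axis-aligned boxes around the left/right brow, left/right eye, nose and
#' mouth of the neutral geometry, constructed to be pairwise disjoint and to
#' contain the full ink support of their feature under any activation of
#' amplitude up to ~3 px. Together they partition the "active" face area;
#' pixels outside every mask are static background or rigid skin.
#'
#' @inheritParams render_face
#' @return Named list of `H x W` logical matrices:
#'   `left_brow`, `right_brow`, `left_eye`, `right_eye`, `nose`, `mouth`.
#' @export
face_region_masks <- function(size = c(96, 96), jitter = c(1, 1)) {
  H <- as.integer(size[1]); W <- as.integer(size[2])
  g <- face_geometry(c(H, W), jitter)
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), times = W), H, W)
  box <- function(x0, x1, y0, y1) X >= x0 & X <= x1 & Y >= y0 & Y <= y1
  brow_y0 <- g$brow_y - 9; brow_y1 <- g$brow_y + 8
  eye_y0 <- brow_y1 + 1
  eye_y1 <- g$eye_y + 1.6 * (g$eye_ry + 3) + 1.5
  nose_x0 <- g$cx - 8.49; nose_x1 <- g$cx + 8.49
  nose_y1 <- g$nose_bot_y + 4 * g$nostril_sigma + 0.49
  mouth_y0 <- nose_y1 + 1
  list(
    left_brow = box(g$cx - g$brow_outer_dx - 6, g$cx - 1.5, brow_y0, brow_y1),
    right_brow = box(g$cx + 1.5, g$cx + g$brow_outer_dx + 6, brow_y0, brow_y1),
    left_eye = box(g$cx - g$eye_dx - 1.6 * g$eye_rx - 2, nose_x0 - 1,
                   eye_y0, eye_y1),
    right_eye = box(nose_x1 + 1, g$cx + g$eye_dx + 1.6 * g$eye_rx + 2,
                    eye_y0, eye_y1),
    nose = box(nose_x0, nose_x1, brow_y1 + 1, nose_y1),
    mouth = box(g$cx - g$mouth_hw - 9, g$cx + g$mouth_hw + 9,
                mouth_y0, min(g$mouth_y + 14, H))
  )
}

# ---- motion profiles --------------------------------------------------------

#' Onset-apex-offset motion profile
#'
#' Returns a function of the frame index giving the motion phase: 0 at and
#' outside the onset and offset frames, 1 at the apex. `"triangular"` rises
#' and falls linearly; `"gaussian"` uses half-Gaussian lobes (sigma = span /
#' 2.5 per side) rescaled to hit 0 at the ends exactly.
#'
#' @param onset,apex,offset 1-based frame indices, `onset <= apex <= offset`.
#' @param shape `"triangular"` or `"gaussian"`.
#' @return Function mapping frame index vectors to phases in `[0, 1]`.
#' @export
motion_profile <- function(onset, apex, offset, shape = c("triangular", "gaussian")) {
  shape <- match.arg(shape)
  if (!(onset <= apex && apex <= offset))
    abort("need onset <= apex <= offset")
  f <- function(t) {
    up <- function(t) {
      if (apex == onset) return(as.numeric(t >= apex))
      if (shape == "triangular") (t - onset) / (apex - onset)
      else {
        s <- (apex - onset) / 2.5
        g <- exp(-(t - apex)^2 / (2 * s^2)); g0 <- exp(-(apex - onset)^2 / (2 * s^2))
        (g - g0) / (1 - g0)
      }
    }
    dn <- function(t) {
      if (offset == apex) return(as.numeric(t <= apex))
      if (shape == "triangular") (offset - t) / (offset - apex)
      else {
        s <- (offset - apex) / 2.5
        g <- exp(-(t - apex)^2 / (2 * s^2)); g0 <- exp(-(offset - apex)^2 / (2 * s^2))
        (g - g0) / (1 - g0)
      }
    }
    v <- ifelse(t <= apex, up(t), dn(t))
    clamp01(ifelse(t < onset | t > offset, 0, v))
  }
  structure(f, onset = onset, apex = apex, offset = offset, shape = shape)
}

# AU activations an emotion drives, at a common amplitude. Basic emotions use
# the basic AU table; compounds use their resolved AU set (prototypical plus
# frequent secondary AUs, conflicts removed).
emotion_activations <- function(emotion, amplitude) {
  emotion <- tolower(emotion)
  aus <- if (is_basic_emotion(emotion)) {
    basic_au_table()[[emotion]]$prototypical
  } else {
    resolve_aus(emotion)$resolved_aus
  }
  aus <- intersect(aus, .supported_aus)
  au_activation(aus, amplitude)
}

#' Generate one synthetic micro-expression sequence
#'
#' Renders `T` frames of a face performing the AUs of `emotion`, with motion
#' phase following `profile` and optional zero-mean Gaussian pixel noise.
#'
#' @param emotion emotion name (basic or compound; see [emotion_names()]).
#' @param amplitude peak AU displacement in pixels.
#' @param T number of frames (>= 3).
#' @param fps frame rate to record.
#' @param profile a [motion_profile()]; default peaks mid-sequence.
#' @param noise_sd standard deviation of additive pixel noise (0 = noise-free).
#' @param seed integer seed controlling texture, geometry jitter and noise.
#' @param subject_id subject identifier; defaults to `"S<seed>"`.
#' @param size `c(H, W)` frame size.
#' @return A [frame_sequence()] with emotion, class and onset/apex/offset
#'   metadata attached.
#' @export
generate_sequence <- function(emotion, amplitude = 1, T = 35, fps = 30,
                              profile = NULL, noise_sd = 0, seed = 1,
                              subject_id = NULL, size = c(96, 96)) {
  if (T < 3) abort("`T` must be >= 3")
  if (amplitude < 0) abort("`amplitude` must be >= 0")
  class_of(emotion) # validates the name
  if (is.null(profile)) {
    profile <- motion_profile(max(1, round(T * 0.15)), round(T * 0.5),
                              min(T, round(T * 0.85)))
  }
  acts <- emotion_activations(emotion, amplitude)
  jitter <- with_preserved_seed(seed * 7 + 1, 1 + runif(2, -0.03, 0.03))
  H <- size[1]; W <- size[2]
  frames <- array(0, c(T, H, W, 1))
  for (t in seq_len(T)) {
    frames[t, , , 1] <- render_face(acts, phase = profile(t), size = size,
                                    texture_seed = seed, jitter = jitter)
  }
  if (noise_sd > 0) {
    noise <- with_preserved_seed(seed * 13 + 2,
                                 array(rnorm(length(frames), 0, noise_sd), dim(frames)))
    frames <- clamp01(frames + noise)
  }
  out <- frame_sequence(frames, fps = fps,
                        subject_id = subject_id %||% paste0("S", seed),
                        emotion = emotion,
                        onset = attr(profile, "onset"),
                        apex = attr(profile, "apex"),
                        offset = attr(profile, "offset"))
  out$jitter <- jitter
  out
}

#' Generate a balanced multi-subject synthetic dataset
#'
#' Subject identity is a per-subject texture seed plus ~3% geometry jitter;
#' each subject contributes `sequences_per_subject` sequences per emotion,
#' so the class histogram is uniform over the requested emotions. Fully
#' deterministic given `seed`.
#'
#' @param n_subjects number of subjects (>= 2, as needed for
#'   leave-one-subject-out evaluation).
#' @param sequences_per_subject sequences per subject per emotion.
#' @param emotions character vector of emotion names.
#' @param seed integer master seed.
#' @inheritParams generate_sequence
#' @return A list with `sequences` (list of [frame_sequence()]) and
#'   `manifest` (tibble: `subject_id, emotion, class, db, onset, apex,
#'   offset, path`; `path` is `NA` until written out).
#' @export
generate_dataset <- function(n_subjects, sequences_per_subject = 1,
                             emotions = basic_emotion_names(), seed = 1,
                             amplitude = 1, T = 35, fps = 30, noise_sd = 0,
                             size = c(96, 96)) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2 (needed for LOSO)")
  if (length(emotions) == 0) abort("`emotions` must not be empty")
  vapply(emotions, class_of, character(1)) # validate
  seqs <- list()
  rows <- list()
  k <- 0
  for (s in seq_len(n_subjects)) {
    subject_seed <- seed * 1000 + s
    for (e in emotions) {
      for (r in seq_len(sequences_per_subject)) {
        k <- k + 1
        # vary the apex position a little per repeat, deterministically
        onset <- max(1, round(T * 0.15))
        offset <- min(T, round(T * 0.85))
        apex <- clamp(round(T * 0.5) + ((s + r + match(e, emotions)) %% 5) - 2,
                      onset, offset)
        prof <- motion_profile(onset, apex, offset)
        # subject identity: one texture/jitter per subject, not per clip
        jitter <- with_preserved_seed(subject_seed, 1 + runif(2, -0.03, 0.03))
        acts <- emotion_activations(e, amplitude)
        frames <- array(0, c(T, size[1], size[2], 1))
        for (t in seq_len(T)) {
          frames[t, , , 1] <- render_face(acts, phase = prof(t), size = size,
                                          texture_seed = subject_seed,
                                          jitter = jitter)
        }
        if (noise_sd > 0) {
          noise <- with_preserved_seed(subject_seed * 100 + k,
                                       array(rnorm(length(frames), 0, noise_sd),
                                             dim(frames)))
          frames <- clamp01(frames + noise)
        }
        sq <- frame_sequence(frames, fps = fps,
                             subject_id = sprintf("sub%02d", s), emotion = e,
                             onset = attr(prof, "onset"),
                             apex = attr(prof, "apex"),
                             offset = attr(prof, "offset"))
        sq$jitter <- jitter
        seqs[[k]] <- sq
        rows[[k]] <- tibble(subject_id = sq$subject_id, emotion = e,
                            class = class_of(e), db = "synthetic",
                            onset = sq$onset, apex = sq$apex,
                            offset = sq$offset, path = NA_character_)
      }
    }
  }
  list(sequences = seqs, manifest = dplyr::bind_rows(rows))
}

#' Textured patch translating sinusoidally (magnification test fixture)
#'
#' A band-limited random texture sampled at sinusoidally shifted coordinates,
#' giving exact sub-pixel horizontal translation `amp_px * sin(2 pi f t /
#' fps)` -- the canonical small-motion input for measuring magnification
#' gain.
#'
#' @param T frames; @param fps frame rate; @param freq motion frequency (Hz).
#' @param amp_px peak translation in pixels.
#' @param size `c(H, W)`; @param seed texture seed.
#' @param fps,freq,size,seed see above.
#' @return A [frame_sequence()] (grayscale).
#' @export
sinusoid_translation_sequence <- function(T = 300, fps = 30, freq = 0.25,
                                          amp_px = 0.3, size = c(64, 64),
                                          seed = 1) {
  H <- size[1]; W <- size[2]
  # band-limited texture: sum of random plane waves (exactly resampleable)
  # wavelengths >= ~25 px keep the amplified motion well inside the
  # first-order (small k * delta) regime that linear magnification assumes
  waves <- with_preserved_seed(seed, {
    n <- 14
    list(kx = runif(n, -0.25, 0.25), ky = runif(n, -0.25, 0.25),
         ph = runif(n, 0, 2 * pi), am = runif(n, 0.5, 1))
  })
  field <- function(xshift) {
    m <- matrix(0, H, W)
    X <- matrix(rep(seq_len(W), each = H), H, W) - xshift
    Y <- matrix(rep(seq_len(H), times = W), H, W)
    for (i in seq_along(waves$kx)) {
      m <- m + waves$am[i] * sin(waves$kx[i] * X + waves$ky[i] * Y + waves$ph[i])
    }
    m
  }
  # fixed normalisation (from the unshifted field) keeps contrast moderate:
  # amplified intensity swings must stay clear of the [0, 1] clip range
  norm <- max(abs(field(0)))
  tex_at <- function(xshift) 0.5 + 0.25 * field(xshift) / norm
  frames <- array(0, c(T, H, W, 1))
  for (t in seq_len(T)) {
    frames[t, , , 1] <- clamp01(tex_at(amp_px * sin(2 * pi * freq * (t - 1) / fps)))
  }
  frame_sequence(frames, fps = fps)
}
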