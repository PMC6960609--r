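# Frame sequences: the common currency of the pipeline.
#
# A frame_sequence holds a T x H x W x C array of intensities in [0, 1]
# (C = 1 grayscale or 3 RGB), the frame rate, and optional per-sequence
# metadata (subject id, emotion label, onset/apex/offset frame indices).
# Frame indices are 1-based throughout, the R convention.

#' Construct a frame sequence
#'
#' @param frames numeric array of intensities in `[0, 1]`: `T x H x W`
#'   (grayscale) or `T x H x W x C` with `C` 1 or 3.
#' @param fps frame rate in frames per second, `> 0`.
#' @param subject_id optional subject identifier string.
#' @param emotion optional emotion name (one of [emotion_names()]).
#' @param onset,apex,offset optional 1-based frame indices with
#'   `1 <= onset <= apex <= offset <= T` when all present.
#' @return An object of class `frame_sequence`.
#' @examples
#' fs <- frame_sequence(array(0.5, c(4, 8, 8)), fps = 30)
#' n_frames(fs)
#' @export
frame_sequence <- function(frames, fps, subject_id = NULL, emotion = NULL,
                           onset = NULL, apex = NULL, offset = NULL) {
  if (!is.array(frames) || !(length(dim(frames)) %in% c(3L, 4L))) {
    abort("`frames` must be a T x H x W (x C) numeric array")
  }
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  d <- dim(frames)
  if (d[1] < 1) abort("a frame_sequence needs at least one frame")
  if (!d[4] %in% c(1L, 3L)) abort("channel count must be 1 or 3")
  if (!is_scalar_number(fps) || fps <= 0) abort("`fps` must be a positive number")
  if (!is.null(emotion)) {
    emotion <- tolower(emotion)
    class_of(emotion) # validates
  }
  idx <- c(onset = onset, apex = apex, offset = offset)
  if (length(idx) > 0 && (any(idx < 1) || any(idx > d[1]))) {
    abort("onset/apex/offset indices must lie in [1, T]")
  }
  if (!is.null(onset) && !is.null(apex) && onset > apex)
    abort("onset must not exceed apex")
  if (!is.null(apex) && !is.null(offset) && apex > offset)
    abort("apex must not exceed offset")
  structure(
    list(frames = frames, fps = fps, subject_id = subject_id,
         emotion = emotion, onset = onset, apex = apex, offset = offset),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d frames, %d x %d px, %d channel(s), %.6g fps\n",
              d[1], d[2], d[3], d[4], x$fps))
  if (!is.null(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (!is.null(x$emotion))
    cat(sprintf("  emotion: %s (class %s)\n", x$emotion, class_of(x$emotion)))
  if (!is.null(x$onset))
    cat(sprintf("  onset/apex/offset: %s/%s/%s\n",
                x$onset, x$apex %||% "-", x$offset %||% "-"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of frames in a sequence
#' @param seq a [frame_sequence()].
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$frames)[1]

#' Extract one frame
#' @param seq a [frame_sequence()].
#' @param t 1-based frame index.
#' @return `H x W` matrix (grayscale) or `H x W x C` array.
#' @export
get_frame <- function(seq, t) {
  d <- dim(seq$frames)
  stopifnot(t >= 1, t <= d[1])
  f <- seq$frames[t, , , , drop = FALSE]
  dim(f) <- d[-1]
  if (d[4] == 1L) dim(f) <- d[2:3]
  f
}

# Replace the frame array, keeping metadata.
set_frames <- function(seq, frames) {
  out <- seq
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  out$frames <- frames
  out
}

# ITU-R BT.601 luma conversion; pass-through for grayscale.
to_grayscale <- function(frame) {
  if (length(dim(frame)) == 2L) return(frame)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

#' Read a frame sequence from a directory of image files
#'
#' Image files (`.png`, `.jpg`, `.jpeg`, `.tif`, `.tiff`) are read in
#' lexicographic filename order. All frames must share the same dimensions.
#' Video containers are not supported: decode to frames first.
#'
#' @param path directory containing the frames.
#' @param fps frame rate to record (frames per second).
#' @param metadata optional one-row data frame or named list with any of
#'   `subject_id`, `emotion`, `onset`, `apex`, `offset`.
#' @return A [frame_sequence()] with intensities in `[0, 1]`.
#' @export
read_sequence <- function(path, fps = 30, metadata = NULL) {
  if (!dir.exists(path)) abort(paste0("no such directory: ", path))
  files <- sort(list.files(path, pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) abort(paste0("no frames found in ", path))
  frames <- lapply(files, read_image_file)
  d1 <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d1)) {
      abort(paste0("frame has inconsistent shape: ", files[i]))
    }
  }
  nc <- if (length(d1) == 2L) 1L else d1[3]
  arr <- array(0, c(length(frames), d1[1], d1[2], nc))
  for (i in seq_along(frames)) arr[i, , , ] <- frames[[i]]
  md <- as.list(metadata %||% list())
  frame_sequence(arr, fps = md$fps %||% fps,
                 subject_id = md$subject_id, emotion = md$emotion,
                 onset = md$onset, apex = md$apex, offset = md$offset)
}

read_image_file <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- tryCatch({
    if (ext == "png") {
      png::readPNG(file)
    } else {
      x <- EBImage::imageData(EBImage::readImage(file))
      # EBImage stores x (columns) first; transpose to rows-first
      if (length(dim(x)) == 2L) t(x) else aperm(x, c(2, 1, 3))
    }
  }, error = function(e) abort(paste0("unreadable image: ", file)))
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3] # drop alpha
  if (length(dim(img)) == 3L && dim(img)[3] == 2L) img <- img[, , 1]   # gray+alpha
  img
}

#' Write a frame sequence as numbered PNG files
#'
#' Frames are written as `frame_0001.png`, `frame_0002.png`, ... with 8-bit
#' depth; reading them back with [read_sequence()] reproduces 8-bit input
#' exactly.
#'
#' @param seq a [frame_sequence()].
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  T_ <- n_frames(seq)
  for (t in seq_len(T_)) {
    png::writePNG(clamp01(get_frame(seq, t)),
                  file.path(path, sprintf("frame_%04d.png", t)))
  }
  invisible(path)
}

#' Resample every frame to a standard size
#'
#' Bilinear resampling of each frame (each channel independently) to the
#' target size; all metadata, fps and the channel count are preserved.
#' The default 190 x 150 (rows x columns) matches the face-crop resolution
#' the pipeline was designed around; note the convention here is
#' height = 190, width = 150.
#'
#' @param seq a [frame_sequence()].
#' @param size integer vector `c(H, W)` target size in pixels.
#' @return A [frame_sequence()] with `H x W` frames.
#' @export
standardize <- function(seq, size = c(190, 150)) {
  size <- as.integer(size)
  if (length(size) != 2 || any(size <= 0)) abort("`size` must be positive c(H, W)")
  d <- dim(seq$frames)
  if (d[2] == size[1] && d[3] == size[2]) return(seq)
  out <- array(0, c(d[1], size[1], size[2], d[4]))
  for (t in seq_len(d[1])) {
    for (ch in seq_len(d[4])) {
      m <- seq$frames[t, , , ch]
      out[t, , , ch] <- EBImage::resize(m, w = size[1], h = size[2],
                                        filter = "bilinear")
    }
  }
  set_frames(seq, out)
}

# ---- sample manifests -------------------------------------------------------

#' Read or write a sample manifest
#'
#' A manifest is a CSV with one row per sequence and columns
#' `subject_id, emotion, class, db, onset, apex, offset, path`. `class` is
#' rederived from `emotion` on read and any mismatch is an error.
#'
#' @param file CSV path.
#' @return `read_manifest()`: a tibble with the columns above.
#' @export
read_manifest <- function(file) {
  df <- as_tibble(read.csv(file, stringsAsFactors = FALSE))
  need <- c("subject_id", "emotion", "class", "db", "onset", "apex", "offset", "path")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    abort(paste0("manifest is missing column(s): ", paste(miss, collapse = ", ")))
  df$subject_id <- as.character(df$subject_id)
  expected <- class_of(df$emotion)
  if (any(df$class != expected))
    abort("manifest `class` column disagrees with class_of(emotion)")
  df[need]
}

#' @rdname read_manifest
#' @param manifest a data frame of sample records.
#' @export
write_manifest <- function(manifest, file) {
  write.csv(as.data.frame(manifest), file, row.names = FALSE)
  invisible(file)
}
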