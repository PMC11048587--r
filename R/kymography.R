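#' Monochrome frame stack
#'
#' Container for a high-speed video recording: a `T x H x W` array of 8-bit
#' monochrome intensities plus the frame rate. Frame indices are 0-based
#' and `time = frame / fps` seconds.
#'
#' @param frames numeric array `T x H x W` with intensities in `[0, 255]`.
#' @param fps frames per second.
#' @param source_id free-text provenance label.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps, source_id = "") {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a T x H x W array", call. = FALSE)
  if (dim(frames)[1] < 1L) stop("frame stack is empty", call. = FALSE)
  stopifnot_scalar_pos(fps, "fps")
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  structure(list(frames = frames, fps = fps, source_id = source_id),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames, %d x %d px, %g fps (%s)\n",
              d[1], d[2], d[3], x$fps,
              if (nzchar(x$source_id)) x$source_id else "unlabelled"))
  invisible(x)
}

#' Digital kymogram
#'
#' Image formed by stacking, over time, the pixel row of each frame at one
#' fixed scanline across the glottis: row `r` of the kymogram is frame `r`
#' of the video, columns index the medial-lateral position.
#'
#' @param rows numeric `T x W` intensity matrix (one row per frame).
#' @param scanline_index 0-based frame row that was sampled.
#' @param fps frames per second of the source stack.
#' @return an object of class `kymogram`.
#' @export
kymogram <- function(rows, scanline_index, fps) {
  if (!is.matrix(rows) || nrow(rows) < 1L)
    stop("`rows` must be a non-empty T x W matrix", call. = FALSE)
  stopifnot_scalar_pos(fps, "fps")
  structure(list(rows = rows, scanline_index = as.integer(scanline_index),
                 fps = fps),
            class = "kymogram")
}

#' @export
print.kymogram <- function(x, ...) {
  cat(sprintf("<kymogram> %d frames x %d px, scanline %d, %g fps\n",
              nrow(x$rows), ncol(x$rows), x$scanline_index, x$fps))
  invisible(x)
}

#' Read and write frame stacks
#'
#' Frame stacks are stored as lossless 8-bit multi-page TIFF. TIFF carries
#' no frame-rate metadata, so `write_frames()` writes a JSON sidecar
#' (`<path>.json`) holding `fps` and `source_id`; `read_frames()` restores
#' the rate from the sidecar, or from `fps_override`, and errors when
#' neither is available. The TIFF round trip is bit-lossless.
#'
#' @param path TIFF file path (`.tif` / `.tiff`).
#' @param fps_override frame rate to use when no sidecar metadata exists
#'   (also takes precedence over the sidecar when given).
#' @param stack a [frame_stack()].
#' @return `read_frames()` returns a [frame_stack()]; `write_frames()`
#'   returns `path` invisibly.
#' @export
read_frames <- function(path, fps_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("no frames decoded from ", path, call. = FALSE)
  pages <- lapply(pages, function(m) {
    if (length(dim(m)) == 3L) {           # colour input: convert to luma
      m <- 0.299 * m[, , 1] + 0.587 * m[, , 2] + 0.114 * m[, , 3]
    }
    m
  })
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- round(pages[[i]] * 255)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  fps <- fps_override %||% meta$fps
  if (is.null(fps))
    stop("no fps metadata for ", path,
         "; pass `fps_override` or provide a JSON sidecar", call. = FALSE)
  frame_stack(arr, fps = as.numeric(fps),
              source_id = as.character(meta$source_id %||% path))
}

#' @rdname read_frames
#' @export
write_frames <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- dim(stack$frames)[1]
  pages <- lapply(seq_len(n), function(i) stack$frames[i, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8, compression = "none")
  jsonlite::write_json(
    list(fps = stack$fps, source_id = stack$source_id),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Preprocessing settings for frame stacks
#'
#' @param brightness_offset additive intensity offset (8-bit units).
#' @param contrast_gain multiplicative gain (> 0).
#' @param gamma gamma exponent (> 0) applied to normalised intensities.
#' @param rotation_deg in-plane rotation, restricted to multiples of 90
#'   degrees (positive = clockwise), used to bring the folds vertical.
#' @param target_size optional `c(H, W)` output size; resizing uses
#'   area-average (box) interpolation, which does not alias the fold edges
#'   when downsizing.
#' @return an object of class `preprocess_settings`.
#' @export
preprocess_settings <- function(brightness_offset = 0, contrast_gain = 1,
                                gamma = 1, rotation_deg = 0,
                                target_size = NULL) {
  stopifnot_scalar_pos(contrast_gain, "contrast_gain")
  stopifnot_scalar_pos(gamma, "gamma")
  if (rotation_deg %% 90 != 0)
    stop("`rotation_deg` must be a multiple of 90", call. = FALSE)
  if (!is.null(target_size) &&
      (length(target_size) != 2L || any(target_size < 1)))
    stop("`target_size` must be c(H, W)", call. = FALSE)
  structure(list(brightness_offset = brightness_offset,
                 contrast_gain = contrast_gain, gamma = gamma,
                 rotation_deg = rotation_deg %% 360,
                 target_size = target_size),
            class = "preprocess_settings")
}

rotate90_stack <- function(arr, quarter_turns) {
  k <- quarter_turns %% 4L
  for (i in seq_len(k)) {
    # clockwise quarter turn: new[t, i, j] = old[t, H - j + 1, i]
    d <- dim(arr)
    arr <- aperm(arr[, d[2]:1, , drop = FALSE], c(1, 3, 2))
  }
  arr
}

# area-average (box) resampling weights mapping `n_in` samples to `n_out`
box_weights <- function(n_out, n_in) {
  w <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j <- floor(lo):min(ceiling(hi) - 1, n_in - 1)
    w[i, j + 1] <- pmin(hi, j + 1) - pmax(lo, j)
  }
  w / scale
}

resize_stack <- function(arr, target) {
  d <- dim(arr)
  rw <- box_weights(target[1], d[2])
  cw <- box_weights(target[2], d[3])
  out <- array(0, dim = c(d[1], target[1], target[2]))
  for (i in seq_len(d[1])) out[i, , ] <- rw %*% arr[i, , ] %*% t(cw)
  out
}

#' Preprocess a frame stack
#'
#' Applies, in this fixed order: gamma correction
#' (`(in/255)^gamma * 255`), contrast gain, brightness offset, clipping to
#' `[0, 255]` and rounding back to 8-bit; then rotation (multiples of 90
#' degrees); then optional area-average resizing (e.g. 960x720 down to
#' 320x240). Identity settings return the input bit-exactly.
#'
#' @param stack a [frame_stack()].
#' @param settings a [preprocess_settings()].
#' @return a [frame_stack()].
#' @export
preprocess <- function(stack, settings = preprocess_settings()) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(settings, "preprocess_settings"))
  s <- settings
  arr <- stack$frames
  if (s$gamma != 1 || s$contrast_gain != 1 || s$brightness_offset != 0) {
    arr <- (arr / 255)^s$gamma * 255 * s$contrast_gain + s$brightness_offset
    arr <- round(clip01(arr, 0, 255))
  }
  if (s$rotation_deg != 0) arr <- rotate90_stack(arr, s$rotation_deg %/% 90)
  if (!is.null(s$target_size)) {
    arr <- resize_stack(arr, s$target_size)
    arr <- clip01(arr, 0, 255)
  }
  frame_stack(arr, fps = stack$fps, source_id = stack$source_id)
}

#' Select the kymography scanline automatically
#'
#' Picks the frame row with the greatest temporal intensity variance
#' (summed across columns), optionally within a region of interest: the
#' folds oscillate there, so variance peaks at the mid-membranous line.
#'
#' @param stack a [frame_stack()].
#' @param roi optional 0-based `c(row0, col0, row1, col1)` inclusive bounds.
#' @return 0-based row index.
#' @export
select_scanline <- function(stack, roi = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  rows <- seq_len(d[2]); cols <- seq_len(d[3])
  if (!is.null(roi)) {
    rows <- (roi[1]:roi[3]) + 1L
    cols <- (roi[2]:roi[4]) + 1L
  }
  v <- vapply(rows, function(r) {
    m <- stack$frames[, r, cols, drop = TRUE]
    sum(apply(m, 2, stats::var))
  }, numeric(1))
  rows[which.max(v)] - 1L
}

#' Extract the digital kymogram at a scanline
#'
#' Row `r` of the kymogram is the sampled scanline of frame `r`; the frame
#' rate is propagated. Permuting frames permutes kymogram rows identically
#' (the extraction is a pure projection).
#'
#' @param stack a [frame_stack()].
#' @param scanline_index 0-based frame row to sample; `NULL` selects it
#'   automatically via [select_scanline()].
#' @return a [kymogram()].
#' @export
extract_kymogram <- function(stack, scanline_index = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  scanline_index <- scanline_index %||% select_scanline(stack)
  if (scanline_index < 0 || scanline_index >= d[2])
    stop(sprintf("scanline_index %d out of range [0, %d]",
                 scanline_index, d[2] - 1L), call. = FALSE)
  rows <- stack$frames[, scanline_index + 1L, , drop = TRUE]
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = d[1])
  kymogram(rows, scanline_index = scanline_index, fps = stack$fps)
}
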