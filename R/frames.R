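#' Construct a frame stream
#'
#' A frame stream is an ordered sequence of frames sharing one geometry:
#' `height x width` pixels with `channels` 8-bit channels (3 for RGB, 1 for
#' grayscale), each frame stamped with a capture time in integer milliseconds
#' on the capturing device's clock. Streams are the common currency of the
#' package: the synthetic generators produce them, the barrier detector and
#' the noise calibration consume them.
#'
#' @param frames list of numeric arrays, each `height x width x channels`
#'   (a plain `height x width` matrix is promoted to one grayscale channel);
#'   values must be integers in `[0, 255]`.
#' @param fps nominal frame rate in frames per second (positive).
#' @param capture_time_ms optional integer vector of per-frame capture times
#'   in milliseconds, strictly increasing. Defaults to the nominal grid
#'   `round(i * 1000 / fps)` for frame index `i = 0, 1, ...`.
#' @param source free-text descriptor of where the stream came from.
#'
#' @return an object of class `frame_stream` with elements `frames`,
#'   `capture_time_ms`, `fps`, `width`, `height`, `channels`, `source`.
#' @seealso [read_frame_sequence()], [make_static_scene()],
#'   [make_crossing_scene()]
#' @export
frame_stream <- function(frames, fps, capture_time_ms = NULL,
                         source = "memory") {
  if (!is.list(frames) || length(frames) < 1L)
    vg_input_error("'frames' must be a non-empty list of pixel arrays")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    vg_input_error("'fps' must be a single positive number")
  frames <- lapply(frames, as_frame_array)
  dims <- vapply(frames, dim, integer(3))
  if (length(frames) > 1L && any(dims[, -1, drop = FALSE] != dims[, 1]))
    vg_format_error("all frames in a stream must share height, width and channels")
  if (is.null(capture_time_ms)) {
    capture_time_ms <- round((seq_along(frames) - 1) * 1000 / fps)
  } else {
    if (length(capture_time_ms) != length(frames))
      vg_input_error("'capture_time_ms' must have one entry per frame")
    if (any(diff(capture_time_ms) <= 0))
      vg_input_error("'capture_time_ms' must be strictly increasing")
    capture_time_ms <- round(capture_time_ms)
  }
  structure(
    list(frames = frames,
         capture_time_ms = as.numeric(capture_time_ms),
         fps = fps,
         height = dims[1, 1], width = dims[2, 1], channels = dims[3, 1],
         source = source),
    class = "frame_stream")
}

# Normalize a frame to an integer H x W x k array and validate the 8-bit range.
as_frame_array <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (!is.array(x) || length(dim(x)) != 3L)
    vg_input_error("each frame must be an H x W or H x W x k array")
  d <- dim(x)
  if (d[1] < 1L || d[2] < 1L || !(d[3] %in% c(1L, 3L)))
    vg_input_error("frames must be at least 1x1 with 1 (grayscale) or 3 (RGB) channels")
  if (anyNA(x) || any(x < 0) || any(x > 255) || any(x != round(x)))
    vg_input_error("pixel values must be integers in [0, 255]")
  storage.mode(x) <- "integer"
  x
}

#' @export
print.frame_stream <- function(x, ...) {
  mode <- if (x$channels == 3L) "RGB" else "grayscale"
  cat(sprintf("Frame stream: %d frames, %dx%d %s, %.6g fps nominal\n",
              length(x$frames), x$width, x$height, mode, x$fps))
  cat(sprintf("  capture times %g..%g ms (%s)\n",
              x$capture_time_ms[1],
              x$capture_time_ms[length(x$capture_time_ms)], x$source))
  invisible(x)
}

#' Number of frames in a stream
#' @param stream a `frame_stream`.
#' @return integer frame count.
#' @export
n_frames <- function(stream) {
  stopifnot(inherits(stream, "frame_stream"))
  length(stream$frames)
}

#' Read a numbered image sequence as a frame stream
#'
#' Reads all `frame_*.png` / `frame_*.ppm` files in a directory, ordered by
#' the numeric part of their names. Capture timestamps come from a
#' `timestamps.csv` sidecar (columns `index`, `capture_time_ms`) when present,
#' otherwise they are synthesized from the nominal frame rate as
#' `round(i * 1000 / fps)`.
#'
#' @param path directory containing at least two image files.
#' @param fps nominal frame rate used to synthesize timestamps.
#' @return a [frame_stream()].
#' @export
read_frame_sequence <- function(path, fps = 25) {
  if (!dir.exists(path)) vg_input_error(sprintf("no such directory: %s", path))
  files <- list.files(path, pattern = "\\.(png|ppm)$", ignore.case = TRUE)
  if (length(files) < 2L)
    vg_input_error("a frame sequence needs at least 2 image files (consecutive pairs are the unit of detection)")
  num <- suppressWarnings(as.numeric(gsub("\\D", "", files)))
  if (anyNA(num)) vg_format_error("image file names must contain a frame number")
  files <- files[order(num)]
  frames <- lapply(file.path(path, files), read_frame_file)
  ts <- NULL
  sidecar <- file.path(path, "timestamps.csv")
  if (file.exists(sidecar)) {
    tab <- utils::read.csv(sidecar)
    if (!all(c("index", "capture_time_ms") %in% names(tab)))
      vg_format_error("timestamps.csv must have columns index, capture_time_ms")
    ts <- tab$capture_time_ms[order(tab$index)]
  }
  frame_stream(frames, fps = fps, capture_time_ms = ts, source = path)
}

read_frame_file <- function(file) {
  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    img <- png::readPNG(file)
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
    round(img * 255)
  } else {
    read_ppm(file)
  }
}

#' Write a frame stream as a numbered image sequence
#'
#' Writes `frame_000001.png` (or ASCII `.ppm`) files plus a `timestamps.csv`
#' sidecar, so that [read_frame_sequence()] round-trips the stream bit-exactly.
#'
#' @param stream a `frame_stream`.
#' @param path output directory (created if needed).
#' @param format `"png"` (default) or `"ppm"` (ASCII P3, RGB only; plain-text).
#' @return `path`, invisibly.
#' @export
write_frame_sequence <- function(stream, path, format = c("png", "ppm")) {
  stopifnot(inherits(stream, "frame_stream"))
  format <- match.arg(format)
  if (format == "ppm" && stream$channels != 3L)
    vg_format_error("PPM output supports RGB streams only")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stream$frames)) {
    file <- file.path(path, sprintf("frame_%06d.%s", i, format))
    if (format == "png") {
      png::writePNG(stream$frames[[i]] / 255, file)
    } else {
      write_ppm(stream$frames[[i]], file)
    }
  }
  utils::write.csv(
    data.frame(index = seq_along(stream$frames) - 1L,
               capture_time_ms = stream$capture_time_ms),
    file.path(path, "timestamps.csv"), row.names = FALSE)
  invisible(path)
}

# Minimal ASCII PPM (P3) I/O; kept so fixtures can live as plain text.
read_ppm <- function(file) {
  toks <- scan(file, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P3") vg_format_error("only ASCII P3 PPM files are supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3]); maxval <- as.integer(toks[4])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h * 3L) vg_format_error("PPM pixel data truncated")
  if (maxval != 255L) vals <- as.integer(round(vals * 255 / maxval))
  # PPM is row-major R,G,B interleaved
  a <- aperm(array(vals, dim = c(3L, w, h)), c(3L, 2L, 1L))
  a
}

write_ppm <- function(frame, file) {
  d <- dim(frame)
  vals <- as.integer(aperm(frame, c(3L, 2L, 1L)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(d[2], d[1]), "255"), con)
  writeLines(paste(vals, collapse = " "), con)
}

#' Convert a frame or stream to grayscale
#'
#' Uses the unweighted channel mean, `round((R + G + B) / 3)`: the barrier's
#' MSE metric treats channels symmetrically, so no perceptual weighting is
#' applied. Grayscale input passes through unchanged.
#'
#' @param x an `H x W x k` frame array or a `frame_stream`.
#' @return same type as the input, with one channel.
#' @export
to_grayscale <- function(x) UseMethod("to_grayscale")

#' @export
to_grayscale.default <- function(x) {
  x <- as_frame_array(x)
  if (dim(x)[3] == 1L) return(x)
  g <- round((x[, , 1] + x[, , 2] + x[, , 3]) / 3)
  dim(g) <- c(dim(x)[1:2], 1L)
  storage.mode(g) <- "integer"
  g
}

#' @export
to_grayscale.frame_stream <- function(x) {
  x$frames <- lapply(x$frames, to_grayscale.default)
  x$channels <- 1L
  x
}

#' Quantize a frame or stream to the RGB565 gamut
#'
#' Emulates the 16-bit RGB565 capture format of low-cost camera modules:
#' red and blue are reduced to 5 bits, green to 6, then expanded back to
#' 8 bits by bit replication. Bit replication maps 0 to 0 and full scale to
#' 255, keeping MSE magnitudes comparable to native 8-bit streams, and is
#' idempotent. Channel values move by at most 7 (R/B) or 3 (G) gray levels.
#'
#' @param x an RGB `H x W x 3` frame array or an RGB `frame_stream`.
#' @return same type as the input, quantized.
#' @export
quantize_rgb565 <- function(x) UseMethod("quantize_rgb565")

#' @export
quantize_rgb565.default <- function(x) {
  x <- as_frame_array(x)
  if (dim(x)[3] != 3L)
    vg_format_error("RGB565 quantization requires a 3-channel RGB frame")
  rep5 <- function(v) { q <- v %/% 8L; q * 8L + q %/% 4L }
  rep6 <- function(v) { q <- v %/% 4L; q * 4L + q %/% 16L }
  x[, , 1] <- rep5(x[, , 1])
  x[, , 2] <- rep6(x[, , 2])
  x[, , 3] <- rep5(x[, , 3])
  storage.mode(x) <- "integer"
  x
}

#' @export
quantize_rgb565.frame_stream <- function(x) {
  x$frames <- lapply(x$frames, quantize_rgb565.default)
  x
}
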