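#' Per-channel noise SD matching a target static-scene MSE
#'
#' For iid Gaussian per-channel sensor noise of standard deviation `sd`, the
#' expected frame-to-frame MSE of a static RGB scene is
#' `3 channels x 2 sd^2 = 6 sd^2` (each channel difference is the difference
#' of two independent draws). Inverting gives `sd = sqrt(target_mse / 6)`:
#' a target MSE of 24 — the middle of the 20-30 band typical of small
#' sensors — corresponds to `sd = 2` gray levels.
#'
#' @param target_mse desired expected static-scene MSE (positive).
#' @return per-channel Gaussian SD in gray levels.
#' @export
calibrate_noise_sd <- function(target_mse) {
  if (!is.numeric(target_mse) || length(target_mse) != 1L ||
      is.na(target_mse) || target_mse <= 0)
    vg_input_error("'target_mse' must be a single positive number")
  sqrt(target_mse / 6)
}

#' Silhouette specification for crossing scenes
#'
#' A solid rectangle standing in for the athlete: it translates horizontally
#' at constant speed across the background. The leading (right) edge starts
#' at `start_col` and the ground-truth crossing time is the continuous-time
#' instant it reaches the scene's `crossing_col`.
#'
#' @param width_px,height_px rectangle size in pixels.
#' @param color RGB triple (0-255); contrast against the background drives
#'   detectability — a silhouette matching the background is invisible to
#'   the barrier, just as a dark shirt before a dark background defeats a
#'   real camera gate.
#' @param speed_px_per_s horizontal speed, pixels per second (positive).
#' @param y_offset top row of the rectangle (0-based).
#' @param start_col column of the leading edge at time 0.
#' @return a list of class `vg_silhouette`.
#' @export
silhouette_spec <- function(width_px = 40, height_px = 160,
                            color = c(225, 225, 225),
                            speed_px_per_s = 500, y_offset = 40,
                            start_col = 30) {
  if (speed_px_per_s <= 0) vg_input_error("silhouette speed must be positive")
  if (width_px < 1 || height_px < 1) vg_input_error("silhouette must be non-empty")
  structure(list(width_px = width_px, height_px = height_px,
                 color = clamp8(rep_len(color, 3)),
                 speed_px_per_s = speed_px_per_s,
                 y_offset = y_offset, start_col = start_col),
            class = "vg_silhouette")
}

#' Synthetic scene specification
#'
#' Recipe for a reproducible camera stream. Defaults emulate the low-cost
#' sensor the system targets: 160x240 (portrait HQVGA) at 25 fps with
#' per-channel Gaussian sensor noise calibrated so the static-scene MSE sits
#' at 24, inside the 20-30 band measured on real hardware.
#'
#' @param width,height frame size in pixels.
#' @param fps frame rate (frames per second).
#' @param duration_s scene duration in seconds.
#' @param background flat RGB triple (0-255).
#' @param noise_sd per-channel Gaussian noise SD in gray levels;
#'   see [calibrate_noise_sd()].
#' @param silhouette a [silhouette_spec()], or `NULL` for a static scene.
#' @param crossing_col 0-based column the ground-truth crossing time refers
#'   to; defaults to the horizontal center.
#' @param lighting_steps optional list of `list(time_s=, delta=)` global
#'   illumination steps (delta per channel, may be scalar).
#' @param flicker optional `list(region=, amplitude=, period_s=)` periodic
#'   background perturbation (e.g. foliage), applied before noise.
#' @param seed integer seed making generation bit-exact reproducible.
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(width = 160, height = 240, fps = 25, duration_s = 2,
                       background = c(120, 120, 120),
                       noise_sd = calibrate_noise_sd(24),
                       silhouette = NULL, crossing_col = width %/% 2,
                       lighting_steps = NULL, flicker = NULL, seed = 1) {
  if (fps <= 0 || duration_s <= 0) vg_input_error("fps and duration_s must be positive")
  if (noise_sd < 0) vg_input_error("noise_sd must be non-negative")
  if (width < 1 || height < 1) vg_input_error("frame must be at least 1x1")
  if (!is.null(silhouette)) {
    stopifnot(inherits(silhouette, "vg_silhouette"))
    if (silhouette$height_px + silhouette$y_offset > height ||
        silhouette$width_px > width)
      vg_input_error("silhouette does not fit inside the frame")
  }
  structure(list(width = width, height = height, fps = fps,
                 duration_s = duration_s,
                 background = clamp8(rep_len(background, 3)),
                 noise_sd = noise_sd, silhouette = silhouette,
                 crossing_col = crossing_col,
                 lighting_steps = lighting_steps, flicker = flicker,
                 seed = seed),
            class = "scene_spec")
}

scene_n_frames <- function(spec) max(2L, round(spec$fps * spec$duration_s))

# Background + optional flicker + noise for one frame; returns H x W x 3.
render_frame <- function(spec, base, t_ms) {
  px <- base
  if (!is.null(spec$flicker)) {
    fl <- spec$flicker
    delta <- fl$amplitude * sin(2 * pi * (t_ms / 1000) / fl$period_s)
    rows <- (fl$region$row_start + 1L):fl$region$row_end
    cols <- (fl$region$col_start + 1L):fl$region$col_end
    px[rows, cols, ] <- px[rows, cols, ] + delta
  }
  if (spec$noise_sd > 0)
    px <- px + stats::rnorm(length(px), 0, spec$noise_sd)
  clamp8(px)
}

apply_lighting_steps <- function(stream, steps) {
  for (st in steps)
    stream <- add_lighting_step(stream, st$time_s, st$delta)
  stream
}

#' Generate a static synthetic scene
#'
#' Flat background plus fresh iid per-channel Gaussian sensor noise in every
#' frame — the setting in which the noise floor `tau` is calibrated.
#' Bit-exact reproducible for a given spec and seed.
#'
#' @param spec a [scene_spec()] with `silhouette = NULL`.
#' @return a [frame_stream()].
#' @export
make_static_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(spec$silhouette))
    vg_input_error("static scenes must have silhouette = NULL; use make_crossing_scene()")
  n <- scene_n_frames(spec)
  base <- array(rep(spec$background, each = spec$height * spec$width),
                dim = c(spec$height, spec$width, 3))
  times <- round((seq_len(n) - 1) * 1000 / spec$fps)
  frames <- with_seed(spec$seed,
    lapply(times, function(t) render_frame(spec, base, t)))
  stream <- frame_stream(frames, fps = spec$fps, capture_time_ms = times,
                         source = "synthetic/static")
  if (!is.null(spec$lighting_steps))
    stream <- apply_lighting_steps(stream, spec$lighting_steps)
  stream
}

#' Generate a crossing scene with ground truth
#'
#' The silhouette translates left-to-right at constant speed over the flat
#' background; noise (and any lighting steps or flicker) is applied after
#' compositing. The ground-truth crossing time is the continuous-time
#' instant the silhouette's leading edge reaches `crossing_col` — it is a
#' property of the motion, independent of the frame rate; only the
#' detector's report is quantized to the frame grid.
#'
#' @param spec a [scene_spec()] with a [silhouette_spec()].
#' @return list with elements `stream` (a [frame_stream()]) and
#'   `ground_truth` (`crossing_time_ms`, `crossing_col`, `spec`).
#' @export
make_crossing_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  sil <- spec$silhouette
  if (is.null(sil))
    vg_input_error("crossing scenes need a silhouette; see silhouette_spec()")
  crossing_time_ms <- (spec$crossing_col - sil$start_col) /
    sil$speed_px_per_s * 1000
  if (crossing_time_ms < 0 || crossing_time_ms > spec$duration_s * 1000)
    vg_groundtruth_error(
      "silhouette never reaches crossing_col within the scene duration")
  n <- scene_n_frames(spec)
  base <- array(rep(spec$background, each = spec$height * spec$width),
                dim = c(spec$height, spec$width, 3))
  times <- round((seq_len(n) - 1) * 1000 / spec$fps)
  rows <- (sil$y_offset + 1L):(sil$y_offset + sil$height_px)
  frames <- with_seed(spec$seed, lapply(times, function(t) {
    px <- base
    lead <- sil$start_col + sil$speed_px_per_s * t / 1000
    # a pixel column is covered when its center lies under the rectangle
    cols <- which(seq_len(spec$width) - 0.5 >= lead - sil$width_px &
                  seq_len(spec$width) - 0.5 < lead)
    if (length(cols))
      px[rows, cols, ] <- rep(sil$color, each = length(rows) * length(cols))
    render_frame(spec, px, t)
  }))
  stream <- frame_stream(frames, fps = spec$fps, capture_time_ms = times,
                         source = "synthetic/crossing")
  if (!is.null(spec$lighting_steps))
    stream <- apply_lighting_steps(stream, spec$lighting_steps)
  list(stream = stream,
       ground_truth = list(crossing_time_ms = crossing_time_ms,
                           crossing_col = spec$crossing_col,
                           spec = spec))
}

#' Apply a global illumination step to a stream
#'
#' Shifts every pixel of every frame at or after `time_s` by `delta`
#' (clamped to the 8-bit range) — the "lights switched on" failure mode that
#' falsely triggers an uncompensated camera gate. An unclamped step of
#' `delta` gray levels per channel produces a single-pair MSE of
#' `3 * delta^2` in any region.
#'
#' @param stream a `frame_stream`.
#' @param time_s step time in seconds.
#' @param delta per-channel shift (scalar or length 3), gray levels.
#' @return the modified stream.
#' @export
add_lighting_step <- function(stream, time_s, delta) {
  stopifnot(inherits(stream, "frame_stream"))
  delta <- rep_len(delta, stream$channels)
  hit <- which(stream$capture_time_ms >= time_s * 1000)
  for (i in hit) {
    f <- stream$frames[[i]]
    for (k in seq_len(stream$channels))
      f[, , k] <- f[, , k] + delta[k]
    stream$frames[[i]] <- clamp8(f)
  }
  stream
}

#' Write / read a scene specification as JSON
#' @param spec a [scene_spec()].
#' @param path JSON file path.
#' @return `path` invisibly; `read_scene_spec` returns the [scene_spec()].
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  x <- unclass(spec)
  if (!is.null(x$silhouette)) x$silhouette <- unclass(x$silhouette)
  if (!is.null(x$flicker)) x$flicker$region <- unclass(x$flicker$region)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  if (!file.exists(path)) vg_input_error(sprintf("no such file: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sil <- NULL
  if (!is.null(x$silhouette) && length(x$silhouette))
    sil <- do.call(silhouette_spec, x$silhouette)
  fl <- NULL
  if (!is.null(x$flicker) && length(x$flicker)) {
    fl <- x$flicker
    fl$region <- do.call(region, as.list(fl$region))
  }
  steps <- NULL
  if (!is.null(x$lighting_steps) && length(x$lighting_steps)) {
    steps <- x$lighting_steps
    if (is.data.frame(steps)) steps <- split(steps, seq_len(nrow(steps)))
  }
  scene_spec(width = x$width, height = x$height, fps = x$fps,
             duration_s = x$duration_s, background = unlist(x$background),
             noise_sd = x$noise_sd, silhouette = sil,
             crossing_col = x$crossing_col, lighting_steps = steps,
             flicker = fl, seed = x$seed)
}
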