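#' Define a barrier region
#'
#' A region is the pixel band over which the gate's frame-to-frame MSE is
#' computed — typically a few columns spanning the full frame height, placed
#' on the measurement line. Coordinates are 0-based with half-open ranges,
#' row-major.
#'
#' @param col_start,col_end half-open column range, 0-based.
#' @param row_start,row_end half-open row range, 0-based.
#' @param label short identifier.
#' @return an object of class `vg_region`.
#' @export
region <- function(col_start, col_end, row_start, row_end, label = "band") {
  vals <- c(col_start, col_end, row_start, row_end)
  if (!is.numeric(vals) || length(vals) != 4L || anyNA(vals) ||
      any(vals != round(vals)) || any(vals < 0))
    vg_config_error("region bounds must be non-negative integers")
  if (col_end <= col_start || row_end <= row_start)
    vg_config_error("region must be non-empty (end bounds are exclusive)")
  structure(list(col_start = as.integer(col_start), col_end = as.integer(col_end),
                 row_start = as.integer(row_start), row_end = as.integer(row_end),
                 label = as.character(label)),
            class = "vg_region")
}

region_n_pixels <- function(r) {
  (r$col_end - r$col_start) * (r$row_end - r$row_start)
}

check_region_bounds <- function(r, height, width) {
  if (r$col_end > width || r$row_end > height)
    vg_config_error(sprintf(
      "region '%s' [rows %d:%d, cols %d:%d) exceeds frame bounds %dx%d",
      r$label, r$row_start, r$row_end, r$col_start, r$col_end, height, width))
  invisible(r)
}

regions_disjoint <- function(a, b) {
  a$col_end <= b$col_start || b$col_end <= a$col_start ||
    a$row_end <= b$row_start || b$row_end <= a$row_start
}

#' Default full-height barrier band
#'
#' A 6-column band spanning the full frame height, centered on
#' `center_col` (the frame's horizontal center by default) — the usual
#' placement for a virtual photoelectric barrier aligned with a measurement
#' line.
#'
#' @param height,width frame dimensions in pixels.
#' @param center_col 0-based column the band is centered on.
#' @param band_width band width in columns.
#' @return a [region()].
#' @export
default_region <- function(height, width, center_col = width %/% 2,
                           band_width = 6L) {
  half <- band_width %/% 2
  region(max(0L, center_col - half),
         min(width, center_col - half + band_width),
         0L, height, label = "center_band")
}

#' Barrier configuration
#'
#' Bundles the gate's detection parameters: one or more disjoint regions
#' (several regions emulate professional dual-beam gates), the sensitivity
#' threshold `theta`, a per-region noise floor `tau`, the color mode, a
#' refractory period suppressing repeat triggers while a single athlete
#' passes, and the convention mapping a triggering frame pair to a timestamp.
#'
#' Because the MSE is invariant to region size, a single `theta` serves all
#' regions; `tau` is estimated per region (see [estimate_noise()]).
#'
#' @param regions a [region()] or list of pairwise-disjoint regions.
#' @param theta positive sensitivity threshold; the default 400 is a
#'   conservative value well above typical sensor-noise MSE (20-30).
#' @param tau non-negative noise floor(s), recycled to one per region.
#'   Defaults to 0, i.e. uncalibrated.
#' @param color_mode `"rgb"` (advised: color separates an athlete from the
#'   background even when brightness does not) or `"grayscale"`.
#' @param refractory_ms post-trigger dead time in ms (default 1000 so one
#'   athlete's limbs and torso yield a single event).
#' @param timestamp_convention which instant of the triggering frame pair is
#'   reported: `"later_frame"` (default; the first frame exhibiting motion),
#'   `"earlier_frame"`, or `"midpoint"`.
#' @return an object of class `barrier_config`.
#' @export
barrier_config <- function(regions, theta = 400, tau = 0,
                           color_mode = c("rgb", "grayscale"),
                           refractory_ms = 1000,
                           timestamp_convention = c("later_frame",
                                                    "earlier_frame",
                                                    "midpoint")) {
  if (inherits(regions, "vg_region")) regions <- list(regions)
  if (!is.list(regions) || length(regions) < 1L ||
      !all(vapply(regions, inherits, logical(1), "vg_region")))
    vg_config_error("'regions' must be one or more vg_region objects")
  if (length(regions) > 1L) {
    for (i in seq_along(regions)[-1]) for (j in seq_len(i - 1L))
      if (!regions_disjoint(regions[[i]], regions[[j]]))
        vg_config_error("barrier regions must be pairwise disjoint")
  }
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    vg_config_error("'theta' must be a single positive number")
  tau <- rep_len(as.numeric(tau), length(regions))
  if (anyNA(tau) || any(tau < 0))
    vg_config_error("'tau' must be non-negative")
  if (!is_count(refractory_ms))
    vg_config_error("'refractory_ms' must be a non-negative number")
  structure(list(regions = regions, theta = theta, tau = tau,
                 color_mode = match.arg(color_mode),
                 refractory_ms = as.numeric(refractory_ms),
                 timestamp_convention = match.arg(timestamp_convention)),
            class = "barrier_config")
}

#' @export
print.barrier_config <- function(x, ...) {
  cat(sprintf("Barrier config: %d region(s), theta=%g, mode=%s, refractory=%g ms\n",
              length(x$regions), x$theta, x$color_mode, x$refractory_ms))
  for (i in seq_along(x$regions)) {
    r <- x$regions[[i]]
    cat(sprintf("  %s: rows [%d,%d) cols [%d,%d), tau=%g\n",
                r$label, r$row_start, r$row_end, r$col_start, r$col_end, x$tau[i]))
  }
  invisible(x)
}

#' Region-banded mean squared error between two frames
#'
#' The barrier's change metric: over the `n` pixels of the region, the mean
#' of the summed squared per-channel differences,
#' \deqn{MSE = \frac{1}{n} \sum_{y \in \Omega} (\Delta r_y)^2 + (\Delta g_y)^2
#'   + (\Delta b_y)^2,}
#' with a single channel term in grayscale mode. Dividing by the pixel count
#' (not pixel-channels) makes the value invariant to region size, so one
#' threshold serves regions of any geometry.
#'
#' @param frame_a,frame_b pixel arrays of identical dimensions.
#' @param region a [region()] within the frame bounds.
#' @param color_mode `"rgb"` or `"grayscale"` (RGB input is converted).
#' @return non-negative numeric; 0 iff the frames agree on every region pixel.
#' @export
mse_diff <- function(frame_a, frame_b, region,
                     color_mode = c("rgb", "grayscale")) {
  color_mode <- match.arg(color_mode)
  frame_a <- as_frame_array(frame_a)
  frame_b <- as_frame_array(frame_b)
  if (!identical(dim(frame_a), dim(frame_b)))
    vg_input_error("frames must share dimensions")
  if (color_mode == "rgb" && dim(frame_a)[3] != 3L)
    vg_input_error("color_mode 'rgb' requires 3-channel frames")
  if (color_mode == "grayscale") {
    frame_a <- to_grayscale.default(frame_a)
    frame_b <- to_grayscale.default(frame_b)
  }
  check_region_bounds(region, dim(frame_a)[1], dim(frame_a)[2])
  rows <- (region$row_start + 1L):region$row_end
  cols <- (region$col_start + 1L):region$col_end
  d <- frame_a[rows, cols, , drop = FALSE] - frame_b[rows, cols, , drop = FALSE]
  sum(as.numeric(d)^2) / region_n_pixels(region)
}

#' Estimate a region's noise floor from a static scene
#'
#' Measures the frame-to-frame MSE over every consecutive pair of a static
#' recording and returns the maximum: the noise floor `tau` that is added to
#' the sensitivity threshold in the trigger decision. The maximum (rather
#' than the mean) also absorbs background perturbations such as moving
#' foliage, provided they occurred during calibration.
#'
#' @param stream a `frame_stream` of a static scene with at least 2 frames.
#' @param region the [region()] to calibrate.
#' @param color_mode `"rgb"` or `"grayscale"`.
#' @return non-negative numeric `tau`.
#' @export
estimate_noise <- function(stream, region, color_mode = c("rgb", "grayscale")) {
  stopifnot(inherits(stream, "frame_stream"))
  color_mode <- match.arg(color_mode)
  if (n_frames(stream) < 2L)
    vg_input_error("noise estimation needs at least 2 frames")
  max(vapply(seq_len(n_frames(stream) - 1L), function(i) {
    mse_diff(stream$frames[[i]], stream$frames[[i + 1L]], region, color_mode)
  }, numeric(1)))
}

#' Barrier trigger decision
#'
#' The binary decision for one frame pair and one region: 1 iff the MSE
#' strictly exceeds `theta + tau`. Strict inequality means the boundary value
#' is not a trigger. Monotone non-decreasing in the MSE and non-increasing in
#' both thresholds.
#'
#' @param mse_value non-negative MSE value(s).
#' @param theta positive sensitivity threshold.
#' @param tau non-negative noise floor.
#' @return integer 0/1, vectorized over `mse_value`.
#' @export
barrier_decision <- function(mse_value, theta = 400, tau = 0) {
  if (!is.numeric(mse_value) || anyNA(mse_value) || any(mse_value < 0))
    vg_input_error("'mse_value' must be non-negative")
  if (!is.numeric(theta) || theta <= 0) vg_config_error("'theta' must be positive")
  if (!is.numeric(tau) || tau < 0) vg_config_error("'tau' must be non-negative")
  as.integer(mse_value > theta + tau)
}

#' Detect gate triggers in a frame stream
#'
#' Slides over consecutive frame pairs and fires when the decision function
#' is 1 for *every* configured region on the same pair (the multi-barrier
#' AND, emulating dual-beam gates that reject limb-only crossings). After an
#' event, pairs whose later frame falls within the refractory period are
#' suppressed.
#'
#' @param stream a `frame_stream` with at least 2 frames.
#' @param config a [barrier_config()] valid for the stream's dimensions.
#' @param gate_id identifier stamped on the events.
#' @return a data frame of class `trigger_events` with columns `gate_id`,
#'   `frame_index` (0-based index of the later frame of the pair),
#'   `device_time_ms`, and `mse_region_0` ... one per region.
#' @export
detect_triggers <- function(stream, config, gate_id = "gate") {
  stopifnot(inherits(stream, "frame_stream"), inherits(config, "barrier_config"))
  if (n_frames(stream) < 2L)
    vg_input_error("trigger detection needs at least 2 frames")
  if (config$color_mode == "rgb" && stream$channels != 3L)
    vg_config_error("config color_mode 'rgb' but stream is grayscale")
  for (r in config$regions) check_region_bounds(r, stream$height, stream$width)

  m <- length(config$regions)
  npairs <- n_frames(stream) - 1L
  mse <- matrix(0, npairs, m)
  for (i in seq_len(npairs)) for (j in seq_len(m)) {
    mse[i, j] <- mse_diff(stream$frames[[i]], stream$frames[[i + 1L]],
                          config$regions[[j]], config$color_mode)
  }
  fired <- rowSums(sweep(mse, 2, config$theta + config$tau, ">")) == m

  t_later <- stream$capture_time_ms[-1]
  t_earlier <- stream$capture_time_ms[-n_frames(stream)]
  stamp <- switch(config$timestamp_convention,
                  later_frame = t_later,
                  earlier_frame = t_earlier,
                  midpoint = (t_earlier + t_later) / 2)

  keep <- logical(npairs)
  last_evt <- -Inf
  for (i in seq_len(npairs)) {
    if (fired[i] && t_later[i] - last_evt >= config$refractory_ms) {
      keep[i] <- TRUE
      last_evt <- t_later[i]
    }
  }
  idx <- which(keep)
  out <- data.frame(gate_id = rep(gate_id, length(idx)),
                    frame_index = idx,  # 0-based index of the later frame
                    device_time_ms = stamp[idx],
                    stringsAsFactors = FALSE)
  msecols <- as.data.frame(mse[idx, , drop = FALSE])
  names(msecols) <- sprintf("mse_region_%d", seq_len(m) - 1L)
  out <- cbind(out, msecols)
  class(out) <- c("trigger_events", "data.frame")
  attr(out, "config") <- config
  out
}

#' Write / read trigger events as CSV
#'
#' @param events a `trigger_events` data frame.
#' @param path CSV file path.
#' @return `path` invisibly; `read_triggers` returns the data frame.
#' @export
write_triggers <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_triggers
#' @export
read_triggers <- function(path) {
  if (!file.exists(path)) vg_input_error(sprintf("no such file: %s", path))
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("trigger_events", "data.frame")
  out
}

#' Write / read a barrier configuration as JSON
#'
#' The on-disk format stores `gate_id`, `theta`, `color_mode`,
#' `refractory_ms`, `timestamp_convention` and a `regions` array whose
#' entries carry the region geometry plus its calibrated `tau`.
#'
#' @param config a [barrier_config()].
#' @param path JSON file path.
#' @param gate_id identifier stored alongside the parameters.
#' @return `path` invisibly; `read_barrier_config` returns a list with
#'   elements `config` and `gate_id`.
#' @export
write_barrier_config <- function(config, path, gate_id = "gate") {
  stopifnot(inherits(config, "barrier_config"))
  regs <- lapply(seq_along(config$regions), function(i) {
    r <- config$regions[[i]]
    list(label = r$label, col_start = r$col_start, col_end = r$col_end,
         row_start = r$row_start, row_end = r$row_end, tau = config$tau[i])
  })
  jsonlite::write_json(
    list(gate_id = gate_id, theta = config$theta,
         color_mode = config$color_mode,
         refractory_ms = config$refractory_ms,
         timestamp_convention = config$timestamp_convention,
         regions = regs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_barrier_config
#' @export
read_barrier_config <- function(path) {
  if (!file.exists(path)) vg_input_error(sprintf("no such file: %s", path))
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) vg_format_error(
                  sprintf("cannot parse config %s: %s", path, conditionMessage(e))))
  if (is.null(x$regions) || length(x$regions) < 1L)
    vg_format_error("config must define at least one region")
  regs <- lapply(x$regions, function(r)
    region(r$col_start, r$col_end, r$row_start, r$row_end,
           label = if (is.null(r$label)) "band" else r$label))
  tau <- vapply(x$regions, function(r)
    if (is.null(r$tau)) 0 else as.numeric(r$tau), numeric(1))
  cfg <- barrier_config(
    regs,
    theta = if (is.null(x$theta)) 400 else x$theta,
    tau = tau,
    color_mode = if (is.null(x$color_mode)) "rgb" else x$color_mode,
    refractory_ms = if (is.null(x$refractory_ms)) 1000 else x$refractory_ms,
    timestamp_convention = if (is.null(x$timestamp_convention)) "later_frame"
                           else x$timestamp_convention)
  list(config = cfg, gate_id = if (is.null(x$gate_id)) "gate" else x$gate_id)
}
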