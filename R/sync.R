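#' Simulate one ping round-trip between controller and gate
#'
#' The controller stamps its clock into a ping at `t_send`; the gate device
#' stamps its own clock `t_device` when it replies; the controller records
#' `t_recv` on reception. With a forward latency `f`, backward latency `b`
#' and a true device-minus-controller offset `o`:
#' `t_device = t_send + f + o` and `t_recv = t_send + f + b`.
#'
#' @param true_offset_ms gate clock minus controller clock, ms.
#' @param forward_latency_ms,backward_latency_ms one-way latencies, ms
#'   (non-negative; vectors are recycled to the same length).
#' @param controller_time_ms controller clock at transmission.
#' @return data frame with columns `t_send`, `t_device`, `t_recv`
#'   (one row per ping).
#' @export
simulate_ping <- function(true_offset_ms, forward_latency_ms,
                          backward_latency_ms, controller_time_ms = 0) {
  if (any(forward_latency_ms < 0) || any(backward_latency_ms < 0))
    vg_input_error("latencies must be non-negative")
  n <- max(length(forward_latency_ms), length(backward_latency_ms),
           length(controller_time_ms))
  f <- rep_len(forward_latency_ms, n)
  b <- rep_len(backward_latency_ms, n)
  t0 <- rep_len(controller_time_ms, n)
  data.frame(t_send = t0,
             t_device = t0 + f + true_offset_ms,
             t_recv = t0 + f + b)
}

#' Simulate a synchronization session of repeated pings
#'
#' Draws per-ping forward and backward latencies independently from a
#' lognormal distribution — transport latency is volatile and right-skewed,
#' ranging from a few to hundreds of milliseconds — and spaces pings at a
#' fixed interval.
#'
#' @param n_pings number of pings (default 20, one synchronization burst).
#' @param true_offset_ms true gate-minus-controller clock offset.
#' @param latency_meanlog,latency_sdlog lognormal parameters of the one-way
#'   latency in ms (defaults give a median of 30 ms).
#' @param interval_ms spacing between ping transmissions.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return data frame of pings as in [simulate_ping()].
#' @export
simulate_ping_session <- function(n_pings = 20, true_offset_ms = 0,
                                  latency_meanlog = log(30),
                                  latency_sdlog = 0.6,
                                  interval_ms = 50, seed = NULL) {
  if (!is_count(n_pings) || n_pings < 1) vg_input_error("'n_pings' must be >= 1")
  with_seed(seed, {
    f <- stats::rlnorm(n_pings, latency_meanlog, latency_sdlog)
    b <- stats::rlnorm(n_pings, latency_meanlog, latency_sdlog)
    simulate_ping(true_offset_ms, f, b,
                  controller_time_ms = (seq_len(n_pings) - 1) * interval_ms)
  })
}

#' Estimate the gate-vs-controller clock offset from pings
#'
#' Cristian-style midpoint estimator: each ping yields
#' `o_i = t_device - (t_send + t_recv) / 2`, exact when forward and backward
#' latencies are equal; its error is `(backward - forward) / 2`, bounded by
#' half the round-trip time. Pings whose round-trip time exceeds 1.5x the
#' median RTT are discarded (heavy-tailed delays bias the mean); if that
#' would discard everything, all pings are kept. The offset is the mean of
#' the surviving per-ping estimates.
#'
#' @param pings data frame with columns `t_send`, `t_device`, `t_recv`.
#' @return an object of class `clock_offset`: `offset_ms`, `n_used`,
#'   `rtt_median_ms` (median RTT over all pings).
#' @export
estimate_offset <- function(pings) {
  if (is.null(pings) || NROW(pings) < 1L)
    vg_input_error("at least one ping is required")
  if (!all(c("t_send", "t_device", "t_recv") %in% names(pings)))
    vg_input_error("pings need columns t_send, t_device, t_recv")
  rtt <- pings$t_recv - pings$t_send
  if (any(rtt < 0)) vg_input_error("negative round-trip time")
  o <- pings$t_device - (pings$t_send + pings$t_recv) / 2
  med <- stats::median(rtt)
  keep <- rtt <= 1.5 * med
  if (!any(keep)) keep <- rep(TRUE, length(rtt))
  structure(list(offset_ms = mean(o[keep]),
                 n_used = sum(keep),
                 rtt_median_ms = med),
            class = "clock_offset")
}

#' @export
print.clock_offset <- function(x, ...) {
  cat(sprintf("Clock offset: %.3f ms (gate - controller), %d ping(s) used, median RTT %.1f ms\n",
              x$offset_ms, x$n_used, x$rtt_median_ms))
  invisible(x)
}

#' Convert between gate-device and controller time domains
#'
#' Gate events are stamped on the gate's own clock; subtracting the
#' estimated offset expresses them on the controller clock so that times
#' from different gates are comparable.
#'
#' @param device_time_ms,controller_time_ms times to convert, ms.
#' @param clock_offset a [estimate_offset()] result or a bare numeric
#'   offset (gate minus controller, ms).
#' @return converted time(s), ms.
#' @export
to_controller_time <- function(device_time_ms, clock_offset) {
  device_time_ms - offset_value(clock_offset)
}

#' @rdname to_controller_time
#' @export
to_device_time <- function(controller_time_ms, clock_offset) {
  controller_time_ms + offset_value(clock_offset)
}

offset_value <- function(x) {
  v <- if (inherits(x, "clock_offset")) x$offset_ms else x
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    vg_input_error("clock offset must be finite")
  v
}

#' Write / read a ping log as CSV
#' @param pings data frame of pings.
#' @param path CSV file path.
#' @return `path` invisibly; `read_ping_log` returns the data frame.
#' @export
write_ping_log <- function(pings, path) {
  utils::write.csv(pings[, c("t_send", "t_device", "t_recv")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_ping_log
#' @export
read_ping_log <- function(path) {
  if (!file.exists(path)) vg_input_error(sprintf("no such file: %s", path))
  utils::read.csv(path)
}
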