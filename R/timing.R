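#' Theoretical timing resolution of a gate
#'
#' A frame-based gate can localize a crossing only to the interval between
#' consecutive evaluations: `1000 / fps` milliseconds. At the 25 fps a
#' low-cost camera microcontroller sustains, that is 40 ms.
#'
#' @param fps evaluation rate in frames per second (positive).
#' @return inter-evaluation interval in milliseconds.
#' @export
resolution_ms <- function(fps) {
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps <= 0)
    vg_input_error("'fps' must be a single positive number")
  1000 / fps
}

#' Pair start- and finish-gate events into timed runs
#'
#' Greedy chronological matching: the earliest unmatched start-gate event is
#' paired with the earliest finish-gate event after it whose elapsed time
#' lies within the plausibility bounds; both events are then consumed.
#' The bounds (default 1-30 s, sensible for a 25 m flying sprint) reject
#' stray pairings such as a limb double-trigger surviving the refractory
#' logic. All event times must already be in the controller time domain
#' (see [to_controller_time()]).
#'
#' @param events_by_gate named list: for each gate id, a numeric vector of
#'   event times (controller ms) or a `trigger_events` data frame with a
#'   `controller_time_ms` column.
#' @param gate_order character vector of at least 2 gate ids; the first is
#'   the start gate, the last the finish gate (the same id may appear twice
#'   for pendulum-style runs on a single gate).
#' @param min_elapsed_s,max_elapsed_s plausibility bounds on the elapsed
#'   time, seconds.
#' @return data frame with columns `run_id`, `start_gate`, `finish_gate`,
#'   `start_time_ms`, `finish_time_ms`, `elapsed_s`, sorted by start time.
#' @export
pair_runs <- function(events_by_gate, gate_order,
                      min_elapsed_s = 1, max_elapsed_s = 30) {
  if (length(gate_order) < 2L)
    vg_config_error("'gate_order' must list at least 2 gates")
  missing <- setdiff(unique(gate_order), names(events_by_gate))
  if (length(missing))
    vg_config_error(sprintf("unknown gate id(s): %s", paste(missing, collapse = ", ")))
  start_gate <- gate_order[1]
  finish_gate <- gate_order[length(gate_order)]
  get_times <- function(x) {
    if (is.data.frame(x)) {
      if (!"controller_time_ms" %in% names(x))
        vg_config_error("event data frames need a controller_time_ms column")
      x <- x$controller_time_ms
    }
    sort(as.numeric(x))
  }
  starts <- get_times(events_by_gate[[start_gate]])
  finishes <- get_times(events_by_gate[[finish_gate]])
  if (start_gate == finish_gate && length(starts)) {
    # pendulum: alternate crossings of one gate act as start/finish
    starts <- finishes <- get_times(events_by_gate[[start_gate]])
  }
  used_f <- rep(FALSE, length(finishes))
  used_s <- rep(FALSE, length(starts))
  runs <- list()
  for (i in seq_along(starts)) {
    if (used_s[i]) next
    el <- (finishes - starts[i]) / 1000
    j <- which(!used_f & el >= min_elapsed_s & el <= max_elapsed_s)
    if (start_gate == finish_gate) j <- setdiff(j, which(used_s))
    if (!length(j)) next
    j <- j[1]
    used_f[j] <- TRUE
    used_s[i] <- TRUE
    if (start_gate == finish_gate) used_s[j] <- TRUE
    runs[[length(runs) + 1L]] <- data.frame(
      start_gate = start_gate, finish_gate = finish_gate,
      start_time_ms = starts[i], finish_time_ms = finishes[j],
      elapsed_s = (finishes[j] - starts[i]) / 1000,
      stringsAsFactors = FALSE)
  }
  out <- if (length(runs)) do.call(rbind, runs) else
    data.frame(start_gate = character(), finish_gate = character(),
               start_time_ms = numeric(), finish_time_ms = numeric(),
               elapsed_s = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$start_time_ms), , drop = FALSE]
  out <- cbind(run_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Write timed runs as CSV
#' @param runs data frame from [pair_runs()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_runs <- function(runs, path) {
  utils::write.csv(runs, path, row.names = FALSE)
  invisible(path)
}
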