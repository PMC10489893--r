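#' Bland-Altman agreement statistics for paired timings
#'
#' Method-comparison statistics between a reference timing system and a
#' candidate: per-trial differences `d_i = candidate - reference`, their
#' mean (bias), sample SD (n-1 denominator), the 95% limits of agreement
#' `bias +/- 1.96 sd`, and the count/percentage of differences inside the
#' limits (boundary values count as within; on continuous data this cannot
#' change the count).
#'
#' @param reference,candidate numeric vectors of paired measurements
#'   (seconds for sprint times), equal length >= 2.
#' @param labels length-2 character: names of the two systems.
#' @return an object of class `bland_altman` with elements `n`, `bias`,
#'   `sd`, `loa_low`, `loa_high`, `n_within`, `pct_within`, `differences`,
#'   `means`, `labels`.
#' @export
bland_altman <- function(reference, candidate,
                         labels = c("reference", "candidate")) {
  if (length(reference) != length(candidate))
    vg_input_error("'reference' and 'candidate' must have equal length")
  n <- length(reference)
  if (n < 2L) vg_input_error("Bland-Altman analysis needs at least 2 pairs")
  if (anyNA(reference) || anyNA(candidate))
    vg_input_error("paired times must not contain NA")
  d <- candidate - reference
  bias <- mean(d)
  s <- stats::sd(d)
  loa_low <- bias - 1.96 * s
  loa_high <- bias + 1.96 * s
  n_within <- sum(d >= loa_low & d <= loa_high)
  structure(list(n = n, bias = bias, sd = s,
                 loa_low = loa_low, loa_high = loa_high,
                 n_within = n_within, pct_within = 100 * n_within / n,
                 differences = d, means = (reference + candidate) / 2,
                 labels = labels),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (%s vs %s), n = %d\n",
              x$labels[2], x$labels[1], x$n))
  cat(sprintf("  bias           %+.4f\n", x$bias))
  cat(sprintf("  SD of diffs     %.4f\n", x$sd))
  cat(sprintf("  95%% LoA        [%+.4f, %+.4f]\n", x$loa_low, x$loa_high))
  cat(sprintf("  within limits   %d / %d (%.2f%%)\n",
              x$n_within, x$n, x$pct_within))
  invisible(x)
}

#' @export
summary.bland_altman <- function(object, ...) print(object, ...)

#' Bland-Altman plot
#'
#' Differences against pair means, with the bias line (solid) and both 95%
#' limits of agreement (dashed).
#'
#' @param x a [bland_altman()] object.
#' @param xlab,ylab,main axis and title labels.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, a list describing the plotted components
#'   (`points`, `bias`, `loa`).
#' @export
plot.bland_altman <- function(x, xlab = "Mean of methods",
                              ylab = "Difference (candidate - reference)",
                              main = "Bland-Altman plot", ...) {
  graphics::plot(x$means, x$differences, xlab = xlab, ylab = ylab,
                 main = main,
                 ylim = range(c(x$differences, x$loa_low, x$loa_high)), ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(list(points = cbind(mean = x$means, difference = x$differences),
                 bias = x$bias, loa = c(x$loa_low, x$loa_high)))
}

#' Simulate a gate-validation experiment
#'
#' Monte-Carlo replicate of a field comparison between a beam-based
#' reference system and the camera gate: true flying-sprint times are drawn
#' uniformly from `true_time_range_s`; the reference reports the truth; the
#' camera system reports the truth plus a Gaussian error of mean `bias_ms`
#' and SD `sd_ms`, snapped to its frame grid (`resolution_ms(fps)`).
#'
#' @param n_trials number of paired runs (>= 2).
#' @param bias_ms,sd_ms mean and SD of the camera system's timing error, ms.
#' @param fps camera evaluation rate; `Inf` disables quantization.
#' @param true_time_range_s length-2 range of true sprint times, seconds.
#' @param seed optional integer seed.
#' @return a [bland_altman()] object.
#' @export
simulate_experiment <- function(n_trials, bias_ms, sd_ms, fps = 25,
                                true_time_range_s = c(3.5, 7.5),
                                seed = NULL) {
  if (!is_count(n_trials) || n_trials < 2) vg_input_error("'n_trials' must be >= 2")
  if (sd_ms < 0) vg_input_error("'sd_ms' must be non-negative")
  if (length(true_time_range_s) != 2L ||
      true_time_range_s[1] <= 0 || diff(true_time_range_s) < 0)
    vg_input_error("'true_time_range_s' must be an increasing positive range")
  with_seed(seed, {
    truth <- stats::runif(n_trials, true_time_range_s[1], true_time_range_s[2])
    cand <- truth + stats::rnorm(n_trials, bias_ms, sd_ms) / 1000
    res_s <- if (is.finite(fps)) resolution_ms(fps) / 1000 else 0
    if (res_s > 0) cand <- round(cand / res_s) * res_s
    bland_altman(truth, cand, labels = c("reference", "camera_gate"))
  })
}

#' Full-pipeline accuracy harness on synthetic sprints
#'
#' For each simulated run, two gates (start/finish) record crossing scenes
#' generated from `scene_template`, separated by `gate_separation_s` of
#' controller time. Each gate has its own clock (random offset, random frame
#' phase) and its noise floor is calibrated once per session from a static
#' scene. Ping-based synchronization estimates the offsets; triggers are
#' detected, converted to controller time, paired into runs and compared
#' against the ground-truth elapsed time. Missed detections are counted and
#' reported, never silently dropped.
#'
#' @param scene_template a [scene_spec()] with a silhouette; per-run scenes
#'   reuse its geometry with run-specific seeds.
#' @param n_runs number of simulated sprints (>= 2).
#' @param gate_separation_s controller-time separation between the two
#'   gates' crossings, seconds.
#' @param seed master seed for the whole session.
#' @param theta sensitivity threshold.
#' @param n_pings pings per synchronization session.
#' @param latency_meanlog,latency_sdlog lognormal one-way latency parameters.
#' @param offset_range_ms range the true device clock offsets are drawn from.
#' @param calib_duration_s duration of the per-gate static calibration scene.
#' @return list of class `e2e_accuracy`: `stats` (a [bland_altman()] on
#'   truth vs measured elapsed seconds), `errors_ms`, `max_abs_error_ms`,
#'   `n_runs`, `n_detected`, `n_missed`, `detection_rate`, `tau` (per gate),
#'   `sync_error_ms` (per gate, estimated minus true offset).
#' @export
end_to_end_accuracy <- function(scene_template, n_runs = 100,
                                gate_separation_s = 4, seed = 1,
                                theta = 400, n_pings = 20,
                                latency_meanlog = log(30),
                                latency_sdlog = 0.5,
                                offset_range_ms = c(-1e5, 1e5),
                                calib_duration_s = 2) {
  stopifnot(inherits(scene_template, "scene_spec"))
  if (is.null(scene_template$silhouette))
    vg_input_error("scene_template needs a silhouette")
  if (!is_count(n_runs) || n_runs < 2) vg_input_error("'n_runs' must be >= 2")
  with_seed(seed, {
    res <- resolution_ms(scene_template$fps)
    sep_ms <- gate_separation_s * 1000
    gates <- c("start", "finish")
    true_offset <- round(stats::runif(2, offset_range_ms[1], offset_range_ms[2]))
    phase <- floor(stats::runif(2, 0, res))
    names(true_offset) <- names(phase) <- gates

    band <- default_region(scene_template$height, scene_template$width,
                           center_col = scene_template$crossing_col)
    # session-time calibration: one static scene per gate
    tau <- vapply(1:2, function(g) {
      st <- scene_template
      st$silhouette <- NULL
      st$duration_s <- calib_duration_s
      st$seed <- sample.int(2^30, 1)
      estimate_noise(make_static_scene(st), band)
    }, numeric(1))
    names(tau) <- gates
    configs <- lapply(1:2, function(g)
      barrier_config(band, theta = theta, tau = tau[g]))

    # connection-time synchronization: one ping session per gate
    est_offset <- vapply(1:2, function(g) {
      pings <- simulate_ping_session(n_pings, true_offset[g],
                                     latency_meanlog, latency_sdlog)
      estimate_offset(pings)$offset_ms
    }, numeric(1))
    names(est_offset) <- gates

    truth_s <- measured_s <- rep(NA_real_, n_runs)
    for (r in seq_len(n_runs)) {
      ctrl_events <- list()
      gt_ms <- numeric(2)
      for (g in 1:2) {
        sp <- scene_template
        sp$seed <- sample.int(2^30, 1)
        # randomize the crossing phase relative to the frame grid: shift the
        # start position by up to one frame interval of travel
        sp$silhouette$start_col <- sp$silhouette$start_col -
          stats::runif(1, 0, sp$silhouette$speed_px_per_s * res / 1000)
        sc <- make_crossing_scene(sp)
        gt_ms[g] <- sc$ground_truth$crossing_time_ms
        # device clock = controller time + true offset; frames start at the
        # gate's phase, and the finish gate's scene begins sep_ms later
        shift <- phase[g] + (g - 1) * sep_ms + true_offset[g]
        sc$stream$capture_time_ms <- sc$stream$capture_time_ms + shift
        ev <- detect_triggers(sc$stream, configs[[g]], gate_id = gates[g])
        ctrl_events[[gates[g]]] <-
          to_controller_time(ev$device_time_ms, est_offset[g])
      }
      truth_s[r] <- (sep_ms + gt_ms[2] + phase[2] - gt_ms[1] - phase[1]) / 1000
      runs <- pair_runs(ctrl_events, gates)
      if (nrow(runs) >= 1L) measured_s[r] <- runs$elapsed_s[1]
    }
    det <- !is.na(measured_s)
    stats_ba <- if (sum(det) >= 2L)
      bland_altman(truth_s[det], measured_s[det],
                   labels = c("ground_truth", "camera_gate")) else NULL
    errors_ms <- (measured_s - truth_s) * 1000
    structure(list(stats = stats_ba,
                   errors_ms = errors_ms,
                   max_abs_error_ms = if (any(det)) max(abs(errors_ms[det])) else NA_real_,
                   n_runs = n_runs, n_detected = sum(det),
                   n_missed = sum(!det),
                   detection_rate = mean(det),
                   tau = tau,
                   sync_error_ms = est_offset - true_offset),
              class = "e2e_accuracy")
  })
}

#' @export
print.e2e_accuracy <- function(x, ...) {
  cat(sprintf("End-to-end synthetic sprint accuracy: %d/%d runs detected (%.0f%%)\n",
              x$n_detected, x$n_runs, 100 * x$detection_rate))
  if (x$n_detected) {
    cat(sprintf("  max |elapsed error|  %.1f ms\n", x$max_abs_error_ms))
    cat(sprintf("  mean error           %+.1f ms\n",
                mean(x$errors_ms, na.rm = TRUE)))
  }
  cat(sprintf("  tau (start/finish)   %.1f / %.1f\n", x$tau[1], x$tau[2]))
  cat(sprintf("  sync error           %+.2f / %+.2f ms\n",
              x$sync_error_ms[1], x$sync_error_ms[2]))
  invisible(x)
}

#' Write agreement statistics as JSON
#' @param x a [bland_altman()] object.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_agreement_stats <- function(x, path) {
  stopifnot(inherits(x, "bland_altman"))
  jsonlite::write_json(
    list(n = x$n, bias_s = x$bias, sd_s = x$sd,
         loa_low_s = x$loa_low, loa_high_s = x$loa_high,
         n_within = x$n_within, pct_within = x$pct_within),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
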