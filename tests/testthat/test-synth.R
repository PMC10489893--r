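test_that("noise calibration inverts the expected-MSE formula", {
  expect_equal(calibrate_noise_sd(24), 2)
  expect_equal(calibrate_noise_sd(6), 1)
  expect_error(calibrate_noise_sd(0), class = "vg_input_error")
  expect_error(calibrate_noise_sd(-3), class = "vg_input_error")
})

test_that("static scenes are reproducible and noiseless scenes are constant", {
  sp0 <- scene_spec(width = 8, height = 10, duration_s = 0.4, noise_sd = 0,
                    seed = 3)
  s0 <- make_static_scene(sp0)
  expect_true(all(vapply(s0$frames, identical, logical(1), s0$frames[[1]])))
  expect_equal(estimate_noise(s0, region(0, 8, 0, 10)), 0)

  sp <- scene_spec(width = 8, height = 10, duration_s = 0.4, seed = 7)
  expect_identical(make_static_scene(sp)$frames, make_static_scene(sp)$frames)
  sp2 <- sp; sp2$seed <- 8
  expect_false(identical(make_static_scene(sp)$frames,
                         make_static_scene(sp2)$frames))
})

test_that("mean consecutive-pair MSE of a calibrated static scene matches 6*sd^2", {
  sp <- narrow_static_spec(seed = 123, width = 40, duration_s = 4)
  s <- make_static_scene(sp)
  reg <- region(0, 40, 0, 160)
  mses <- vapply(seq_len(n_frames(s) - 1), function(i)
    mse_diff(s$frames[[i]], s$frames[[i + 1]], reg), numeric(1))
  # rounding to gray levels adds ~2/12 per channel pair on top of 6*sd^2
  expect_equal(mean(mses), 6 * sp$noise_sd^2, tolerance = 0.05)
})

test_that("crossing ground truth is continuous time, independent of fps", {
  sil <- silhouette_spec(width_px = 30, height_px = 100, y_offset = 10,
                         speed_px_per_s = 500, start_col = 20)
  for (fps in c(25, 40)) {
    sp <- scene_spec(width = 160, height = 120, fps = fps, duration_s = 1,
                     noise_sd = 0, silhouette = sil, crossing_col = 120,
                     seed = 1)
    sc <- make_crossing_scene(sp)
    expect_equal(sc$ground_truth$crossing_time_ms, 200)  # 100 px / 500 px/s
  }
  # silhouette that never reaches the line
  sp_bad <- scene_spec(width = 160, height = 120, duration_s = 0.1,
                       noise_sd = 0, silhouette = sil, crossing_col = 120)
  expect_error(make_crossing_scene(sp_bad), class = "vg_groundtruth_error")
  expect_error(make_static_scene(sp_bad), class = "vg_input_error")
})

test_that("a high-contrast crossing triggers near the ground truth; an invisible one never does", {
  tpl <- narrow_crossing_template(seed = 77)
  sc <- make_crossing_scene(tpl)
  band <- default_region(tpl$height, tpl$width)
  tau <- estimate_noise(make_static_scene(narrow_static_spec(seed = 78,
                                                             width = tpl$width,
                                                             duration_s = 2)),
                        band)
  cfg <- barrier_config(band, theta = 400, tau = tau)
  ev <- detect_triggers(sc$stream, cfg, "A")
  expect_equal(nrow(ev), 1L)
  expect_lte(abs(ev$device_time_ms - sc$ground_truth$crossing_time_ms),
             2 * resolution_ms(tpl$fps))

  # zero-contrast silhouette: color equals the background
  tpl0 <- tpl
  tpl0$silhouette$color <- tpl0$background
  sc0 <- make_crossing_scene(tpl0)
  expect_equal(nrow(detect_triggers(sc0$stream, cfg, "A")), 0L)
})

test_that("lighting steps shift pixels and reproduce the documented false positive", {
  sp <- scene_spec(width = 8, height = 10, duration_s = 0.4, noise_sd = 0,
                   background = c(100, 100, 100), seed = 1)
  s <- make_static_scene(sp)
  reg <- region(0, 8, 0, 10)

  s_same <- add_lighting_step(s, 0.2, 0)
  expect_identical(s_same$frames, s$frames)

  s_step <- add_lighting_step(s, 0.2, c(40, 40, 40))
  i <- which(s$capture_time_ms >= 200)[1]
  expect_equal(mse_diff(s_step$frames[[i - 1]], s_step$frames[[i]], reg),
               3 * 40^2)   # unclamped: background 100 + 40 stays in range
  expect_equal(mse_diff(s_step$frames[[i]], s_step$frames[[i + 1]], reg), 0)

  # the step exceeds theta + tau: a false trigger, the documented failure mode
  cfg <- barrier_config(reg, theta = 400, tau = 30)
  ev <- detect_triggers(s_step, cfg, "A")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$device_time_ms, s$capture_time_ms[i])
})

test_that("clamping bounds lighting steps at the 8-bit range", {
  sp <- scene_spec(width = 4, height = 4, duration_s = 0.2, noise_sd = 0,
                   background = c(240, 240, 240), seed = 1)
  s <- add_lighting_step(make_static_scene(sp), 0, 40)
  expect_true(all(vapply(s$frames, max, numeric(1)) == 255))
})

test_that("scene specifications round-trip through JSON", {
  sil <- silhouette_spec(width_px = 30, height_px = 100, y_offset = 10,
                         start_col = 20)
  sp <- scene_spec(width = 160, height = 120, duration_s = 1.5,
                   silhouette = sil, crossing_col = 100, seed = 42)
  path <- withr::local_tempfile(fileext = ".json")
  write_scene_spec(sp, path)
  sp2 <- read_scene_spec(path)
  expect_equal(sp2$width, sp$width)
  expect_equal(sp2$silhouette$start_col, 20)
  expect_equal(sp2$crossing_col, 100)
  expect_identical(make_crossing_scene(sp2)$stream$frames,
                   make_crossing_scene(sp)$stream$frames)
})
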