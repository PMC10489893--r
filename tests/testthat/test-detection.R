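test_that("region-banded MSE matches hand-computed cases", {
  a <- flat_rgb(4, 4)
  expect_equal(mse_diff(a, a, region(0, 4, 0, 4)), 0)

  b <- a; b[1, 1, ] <- c(3L, 4L, 0L)
  r1 <- region(0, 1, 0, 1)
  expect_equal(mse_diff(a, b, r1), 25)        # 9 + 16 + 0 over 1 pixel
  expect_equal(mse_diff(b, a, r1), 25)        # symmetric

  cc <- a; cc[1, 1:2, ] <- 1L                 # two pixels differing by (1,1,1)
  expect_equal(mse_diff(a, cc, region(0, 2, 0, 1)), 3)
})

test_that("MSE handles grayscale mode with a single channel term", {
  a <- array(10L, c(2, 2, 1)); b <- array(13L, c(2, 2, 1))
  expect_equal(mse_diff(a, b, region(0, 2, 0, 2), "grayscale"), 9)
  # RGB input is collapsed first: (30,30,30) vs (33,33,33) -> gray 30 vs 33
  ar <- flat_rgb(2, 2, c(30, 30, 30)); br <- flat_rgb(2, 2, c(33, 33, 33))
  expect_equal(mse_diff(ar, br, region(0, 2, 0, 2), "grayscale"), 9)
})

test_that("MSE equals an independent brute-force per-pixel oracle", {
  set.seed(31)
  for (i in 1:25) {
    h <- sample(2:16, 1); w <- sample(2:16, 1)
    k <- sample(c(1L, 3L), 1)
    a <- rand_frame(h, w, k); b <- rand_frame(h, w, k)
    reg <- rand_region(h, w)
    mode <- if (k == 3L) "rgb" else "grayscale"
    got <- mse_diff(a, b, reg, mode)
    expect_equal(got, brute_mse(a, b, reg), tolerance = 1e-12)
  }
})

test_that("MSE is invariant to tiling a region's content", {
  set.seed(32)
  a1 <- rand_frame(4, 3); b1 <- rand_frame(4, 3)
  tile <- function(f, p) {
    out <- array(0L, c(4, 3 * p, 3))
    for (i in seq_len(p)) out[, (i - 1) * 3 + 1:3, ] <- f
    out
  }
  base <- mse_diff(a1, b1, region(0, 3, 0, 4))
  for (p in c(2, 5)) {
    expect_equal(mse_diff(tile(a1, p), tile(b1, p), region(0, 3 * p, 0, 4)),
                 base)
  }
})

test_that("MSE rejects out-of-bounds regions and mismatched frames", {
  a <- flat_rgb(4, 4)
  expect_error(mse_diff(a, a, region(0, 5, 0, 4)), class = "vg_config_error")
  expect_error(mse_diff(a, flat_rgb(4, 5), region(0, 2, 0, 2)),
               class = "vg_input_error")
})

test_that("noise estimation returns the maximum consecutive-pair MSE", {
  f <- flat_rgb(2, 2)
  ident <- stream_of(replicate(5, f, simplify = FALSE))
  expect_equal(estimate_noise(ident, region(0, 2, 0, 2)), 0)

  # consecutive-pair MSEs by construction: {4, 25, 9} over one gray pixel
  g <- function(v) array(as.integer(v), c(1, 1, 1))
  s <- stream_of(list(g(10), g(12), g(17), g(14)))
  expect_equal(estimate_noise(s, region(0, 1, 0, 1), "grayscale"), 25)

  expect_error(estimate_noise(stream_of(list(f)), region(0, 2, 0, 2)),
               class = "vg_input_error")
})

test_that("trigger decision uses a strict threshold and is monotone", {
  expect_equal(barrier_decision(425, 400, 25), 0L)      # boundary: no trigger
  expect_equal(barrier_decision(425.01, 400, 25), 1L)
  expect_equal(barrier_decision(0, 400, 0), 0L)
  expect_error(barrier_decision(-1, 400, 0), class = "vg_input_error")

  set.seed(33)
  for (i in 1:200) {
    mse <- runif(1, 0, 1000); theta <- runif(1, 1, 800); tau <- runif(1, 0, 60)
    d0 <- barrier_decision(mse, theta, tau)
    expect_gte(barrier_decision(mse + runif(1, 0, 500), theta, tau), d0)
    expect_lte(barrier_decision(mse, theta + runif(1, 0, 500), tau), d0)
    expect_lte(barrier_decision(mse, theta, tau + runif(1, 0, 500)), d0)
  }
})

test_that("a sweeping high-contrast edge yields exactly one trigger at the first exceeding pair", {
  # 1x8 gray strip; an edge (value 200 on background 0) advances one column
  # per frame through a 2-column band
  frames <- lapply(0:7, function(pos) {
    f <- array(0L, c(1, 8, 1))
    if (pos > 0) f[1, 1:pos, 1] <- 200L
    f
  })
  s <- stream_of(frames, fps = 25)
  band <- region(3, 5, 0, 1)
  cfg <- barrier_config(band, theta = 400, tau = 0, color_mode = "grayscale",
                        refractory_ms = 1000)
  # pair MSEs in band: 0,0,0, 20000, 20000, 0, 0 -> first exceed at pair 4
  ev <- detect_triggers(s, cfg, "A")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$frame_index, 4L)
  expect_equal(ev$device_time_ms, s$capture_time_ms[5])
  expect_equal(ev$mse_region_0, 200^2 / 2)
})

test_that("timestamp conventions report later frame, earlier frame or midpoint", {
  g <- function(v) array(as.integer(v), c(1, 1, 1))
  s <- stream_of(list(g(0), g(200), g(200)))
  for (conv in c("later_frame", "earlier_frame", "midpoint")) {
    cfg <- barrier_config(region(0, 1, 0, 1), theta = 400, tau = 0,
                          color_mode = "grayscale",
                          timestamp_convention = conv)
    ev <- detect_triggers(s, cfg, "A")
    expect_equal(ev$device_time_ms,
                 switch(conv, later_frame = 40, earlier_frame = 0, midpoint = 20))
  }
})

test_that("refractory period suppresses repeat triggers and separates events", {
  g <- function(v) array(as.integer(v), c(1, 1, 1))
  # alternating 0/200 every frame: every pair exceeds the threshold
  s <- stream_of(lapply(rep(c(0, 200), 10), g), fps = 25)
  cfg <- barrier_config(region(0, 1, 0, 1), theta = 400, tau = 0,
                        color_mode = "grayscale", refractory_ms = 200)
  ev <- detect_triggers(s, cfg, "A")
  expect_true(all(diff(ev$device_time_ms) >= 200))
  expect_equal(ev$device_time_ms, c(40, 240, 440, 640))
  # refractory 0 keeps every firing pair
  cfg0 <- barrier_config(region(0, 1, 0, 1), theta = 400, tau = 0,
                         color_mode = "grayscale", refractory_ms = 0)
  expect_equal(nrow(detect_triggers(s, cfg0, "A")), 19L)
})

test_that("multi-barrier fires only when all regions fire on the same pair", {
  # object crosses only the left of two bands
  frames <- lapply(0:3, function(pos) {
    f <- array(0L, c(2, 8, 1))
    if (pos > 0) f[, pos, 1] <- 200L
    f
  })
  s <- stream_of(frames)
  left <- region(0, 3, 0, 2); right <- region(5, 8, 0, 2)
  cfg2 <- barrier_config(list(left, right), theta = 400, tau = 0,
                         color_mode = "grayscale")
  expect_equal(nrow(detect_triggers(s, cfg2, "A")), 0L)
  cfg1 <- barrier_config(left, theta = 400, tau = 0, color_mode = "grayscale")
  expect_gt(nrow(detect_triggers(s, cfg1, "A")), 0L)
})

test_that("multi-barrier triggering pairs are a subset of each region's own pairs", {
  set.seed(34)
  for (i in 1:60) {
    frames <- replicate(4, rand_frame(6, 8, 1), simplify = FALSE)
    s <- stream_of(frames)
    r1 <- region(0, 4, 0, 6); r2 <- region(4, 8, 0, 6)
    theta <- runif(1, 1000, 14000)
    pairs_of <- function(regs, tau) {
      cfg <- barrier_config(regs, theta = theta, tau = tau,
                            color_mode = "grayscale", refractory_ms = 0)
      detect_triggers(s, cfg, "A")$frame_index
    }
    taus <- runif(2, 0, 500)
    joint <- pairs_of(list(r1, r2), taus)
    expect_true(all(joint %in% pairs_of(r1, taus[1])))
    expect_true(all(joint %in% pairs_of(r2, taus[2])))
  }
})

test_that("barrier configs are validated", {
  r <- region(0, 2, 0, 2)
  expect_error(barrier_config(r, theta = 0), class = "vg_config_error")
  expect_error(barrier_config(r, tau = -1), class = "vg_config_error")
  expect_error(barrier_config(list(r, region(1, 3, 0, 2))),
               class = "vg_config_error")  # overlapping regions
  expect_error(region(2, 2, 0, 1), class = "vg_config_error")
})

test_that("barrier config JSON round-trips including calibrated tau", {
  cfg <- barrier_config(list(region(0, 3, 0, 4, "left"), region(5, 8, 0, 4, "right")),
                        theta = 350, tau = c(21.5, 27.25),
                        color_mode = "grayscale", refractory_ms = 800,
                        timestamp_convention = "midpoint")
  path <- withr::local_tempfile(fileext = ".json")
  write_barrier_config(cfg, path, gate_id = "g7")
  back <- read_barrier_config(path)
  expect_equal(back$gate_id, "g7")
  expect_equal(back$config$theta, 350)
  expect_equal(back$config$tau, c(21.5, 27.25))
  expect_equal(back$config$timestamp_convention, "midpoint")
  expect_equal(back$config$regions[[2]]$col_start, 5L)
})
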