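# Small programmatic fixtures and independent oracles shared by the tests.

# Flat RGB frame of one color.
flat_rgb <- function(h, w, color = c(0, 0, 0)) {
  array(rep(as.integer(color), each = h * w), dim = c(h, w, 3))
}

# Uniform random 8-bit frame.
rand_frame <- function(h, w, k = 3) {
  array(sample.int(256L, h * w * k, replace = TRUE) - 1L, dim = c(h, w, k))
}

# Random in-bounds region ("pick" avoids sample()'s scalar expansion).
rand_region <- function(h, w) {
  pick <- function(v) v[sample.int(length(v), 1)]
  c0 <- pick(seq_len(w)) - 1L; c1 <- pick((c0 + 1):w)
  r0 <- pick(seq_len(h)) - 1L; r1 <- pick((r0 + 1):h)
  region(c0, c1, r0, r1)
}

# Independent brute-force oracle for the region-banded MSE: explicit
# per-pixel double loop, no vectorization shared with the implementation.
brute_mse <- function(a, b, reg) {
  total <- 0
  npix <- 0
  for (row in (reg$row_start + 1):reg$row_end) {
    for (col in (reg$col_start + 1):reg$col_end) {
      npix <- npix + 1
      for (k in seq_len(dim(a)[3])) {
        total <- total + (as.numeric(a[row, col, k]) - as.numeric(b[row, col, k]))^2
      }
    }
  }
  total / npix
}

# Independent brute-force Bland-Altman recomputation.
brute_bland_altman <- function(ref, cand) {
  n <- length(ref)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- cand[i] - ref[i]
  m <- sum(d) / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (d[i] - m)^2
  s <- sqrt(ss / (n - 1))
  lo <- m - 1.96 * s; hi <- m + 1.96 * s
  nw <- 0
  for (i in seq_len(n)) if (d[i] >= lo && d[i] <= hi) nw <- nw + 1
  list(bias = m, sd = s, loa_low = lo, loa_high = hi,
       n_within = nw, pct_within = 100 * nw / n)
}

# Stream of hand-built frames at a nominal fps.
stream_of <- function(frames, fps = 25) frame_stream(frames, fps = fps)

# Narrow-frame scene template used by the heavier simulations: the
# detection band and its full-height pixel count match the default sensor;
# columns outside the band carry no information, so the width is trimmed.
narrow_static_spec <- function(seed, width = 24, height = 160,
                               duration_s = 6) {
  scene_spec(width = width, height = height, duration_s = duration_s,
             seed = seed)
}

narrow_crossing_template <- function(seed = 1, width = 120, height = 160) {
  sil <- silhouette_spec(width_px = 40, height_px = 120, y_offset = 20,
                         color = c(225, 225, 225), speed_px_per_s = 500,
                         start_col = 30)
  scene_spec(width = width, height = height, duration_s = 1,
             silhouette = sil, seed = seed)
}
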