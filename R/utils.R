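# Internal helpers: classed error conditions and RNG hygiene.

vg_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vg_error", "error")))
}

vg_input_error  <- function(msg) vg_error(msg, "vg_input_error")
vg_config_error <- function(msg) vg_error(msg, "vg_config_error")
vg_format_error <- function(msg) vg_error(msg, "vg_format_error")
vg_usage_error  <- function(msg) vg_error(msg, "vg_usage_error")
vg_groundtruth_error <- function(msg) vg_error(msg, "vg_groundtruth_error")

# Run code under a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    vg_input_error("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Clamp to the 8-bit range and round to integer gray levels.
clamp8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
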