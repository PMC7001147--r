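# internal helpers shared across modules

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

wrap_deg <- function(x) {
  out <- x %% 360
  # guard against 360 - eps folding artefacts from floating point
  out[abs(out - 360) < 1e-9] <- 0
  out
}

# Deterministic child seed derived from a top-level seed and integer keys.
# Kept below 2^31 - 1 so it is always a valid R integer seed; adding keys
# (e.g. more subjects) never perturbs streams for existing keys.
child_seed <- function(seed, ...) {
  keys <- c(...)
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (k in keys) {
    h <- (h * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(h)
}

stop_envtacs <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_envtacs(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    stop_envtacs(sprintf("`%s` must be > 0", name))
  }
  invisible(x)
}
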