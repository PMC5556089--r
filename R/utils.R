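# Internal helpers shared across modules.

# Run `code` under a fixed seed without disturbing the caller's RNG state;
# a NULL seed leaves the RNG stream untouched.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# Deterministic per-stream child seed, kept below 2^31 so it is a valid
# R integer seed.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# Round half away from zero (round() in R rounds half to even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}
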