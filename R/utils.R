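# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators are pure functions of their
# seed and never perturb the session stream.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed < 0 || seed != floor(seed)) {
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic seed fan-out: one global seed plus small counters (a, b)
# yield per-stage / per-subject seeds, all < 2^31 so they fit R integers.
derive_seed <- function(seed, a, b = 0L) {
  ((seed %% 50021) * 42013 + a * 389 + b) %% 2147483647
}

stop_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x == floor(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
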