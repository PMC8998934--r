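# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# All stochastic operations in the package route their randomness through this,
# so no function leaves a footprint on .Random.seed.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Round half away from zero (printed percentages in reports use this rule;
# base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Truncate (not round) to `digits` decimals, as printed constants often are.
truncate_decimals <- function(x, digits) {
  stopifnot(digits >= 0)
  trunc(x * 10^digits) / 10^digits
}

stop_t2flux <- function(...) stop(..., call. = FALSE)

warn_t2flux <- function(...) warning(..., call. = FALSE)
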