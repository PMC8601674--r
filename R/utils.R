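# internal validation / RNG helpers

stop_if <- function(cond, ..., call. = FALSE) {
  if (isTRUE(cond)) stop(..., call. = call.)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  stop_if(!is_scalar_num(x), sprintf("'%s' must be a finite numeric scalar", name))
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  stop_if(!(lo_ok && hi_ok),
          sprintf("'%s' = %g out of range %s%g, %g%s", name, x,
                  if (open_lower) "(" else "[", lower, upper,
                  if (open_upper) ")" else "]"))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# the global stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# deterministic small-integer hash for (seed, t) pairs; keeps jitter
# reproducible per sampling timestamp without consuming the global stream
hash_seed <- function(seed, t) {
  s <- (as.numeric(seed) * 69069 + round(as.numeric(t) * 1e4) * 7919) %%
    2147483647
  as.integer(s)
}
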