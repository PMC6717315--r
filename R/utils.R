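# internal helpers

# Evaluate `code` with the R RNG seeded to `seed`, restoring any previous
# RNG state afterwards.  Every stochastic operation in the package routes
# its randomness through this helper so no global RNG state leaks.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# derive a per-replica / per-stage sub-seed, kept inside 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 ||
      x != floor(x))
    stop(sprintf("'%s' must be a single non-negative integer", name),
         call. = FALSE)
  invisible(x)
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)
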