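# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

stop_ct <- function(...) stop(..., call. = FALSE)

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop_ct(what, " must be finite and numeric")
  invisible(x)
}
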