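# Internal helpers shared across the package.

# Round half away from zero. Count estimates must round 0.5 up in magnitude
# regardless of the platform's banker's rounding.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores (or
# removes) .Random.seed afterwards so callers' RNG streams are untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
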