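# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.  All seeded generators
# in the package route through this so that a fixed seed gives
# bit-identical output without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop(sprintf("'%s' must be a %s finite number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  invisible(x)
}

# multiplicative log-normal noise with coefficient of variation `cv`
# (mean 1, sd = cv)
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}
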