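# Internal helpers shared across modules.

# Deterministic sub-stream seeding: every generator call derives its own seed
# from (user seed, purpose tag) so calls are independent and reproducible.
.mix_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483629)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
.with_seed <- function(seed, tag, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(.mix_seed(seed, tag))
  expr
}

# Trapezoidal integral of y over x.
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  invisible(x)
}
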