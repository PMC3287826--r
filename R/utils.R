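# Internal numerics and RNG helpers.

#' Numerically stable log(1 + exp(x))
#'
#' Piecewise evaluation following the standard accurate-computation scheme,
#' exact to double precision over the whole real line.
#'
#' @param x numeric vector.
#' @return log(1 + exp(x)), elementwise.
#' @keywords internal
#' @noRd
log1pexp <- function(x) {
  out <- numeric(length(x))
  lo <- x <= -37
  mid <- !lo & x <= 18
  hi1 <- x > 18 & x <= 33.3
  hi2 <- x > 33.3
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out[hi1] <- x[hi1] + exp(-x[hi1])
  out[hi2] <- x[hi2]
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# user's stream.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Deterministic child seed from (master seed, component tag, index), kept
# inside the 32-bit signed range. Arithmetic stays below 2^53 so doubles are
# exact.
derive_seed <- function(master, component, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(component)) * seq_along(utf8ToInt(as.character(component))))
  s <- (abs(master) %% 2147483647) * 48271 %% 2147483647
  s <- (s + h * 69621 + (index %% 2147483647) * 16807) %% 2147483647
  as.integer(s + 1L)
}

# Clopper-Pearson interval for a binomial proportion.
binom_ci <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower = lower, upper = upper)
}
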