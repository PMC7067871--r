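# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Rank-based two-sided Monte Carlo p-value: observed statistic against
# n_perm null draws, with the +1 inclusion of the observed value.
perm_p_two_sided <- function(obs, null) {
  n <- length(null)
  p_lo <- (1 + sum(null <= obs)) / (n + 1)
  p_hi <- (1 + sum(null >= obs)) / (n + 1)
  min(1, 2 * min(p_lo, p_hi))
}

# Order-statistic 95% envelope: with k = floor(alpha*(n+1)) the chance of a
# null-consistent observation falling outside [lo, hi] is exactly 2k/(n+1).
perm_envelope <- function(null, alpha = 0.025) {
  s <- sort(null)
  k <- max(1L, floor(alpha * (length(null) + 1)))
  c(lower = s[k], upper = s[length(null) + 1L - k])
}
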