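# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit. seed = NULL leaves the RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Hurwitz zeta  sum_{j>=0} (q + j)^(-s)  for s > 1, q > 0.
# Direct sum over the first `nterms` terms plus an Euler-Maclaurin tail;
# accurate to ~1e-14 for s in (1, 50].
hurwitz_zeta <- function(s, q, nterms = 1000L) {
  stopifnot(s > 1, q > 0)
  j <- 0:(nterms - 1L)
  head_sum <- sum((q + j)^(-s))
  N <- q + nterms
  tail_sum <- N^(1 - s) / (s - 1) + 0.5 * N^(-s) +
    s * N^(-s - 1) / 12 - s * (s + 1) * (s + 2) * N^(-s - 3) / 720
  head_sum + tail_sum
}

# log(exp(-a) - exp(-b)) for b > a, avoiding cancellation.
log_exp_diff <- function(a, b) {
  d <- b - a
  -a + log1p(-exp(-d))
}

# logsumexp along rows of a matrix (or of a vector).
logsumexp <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 1L, max)
    m + log(rowSums(exp(x - m)))
  } else {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1L, ]^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
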