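# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by the most literal route available (double loops,
# quadrature, grids) and must stay free of the package's own code paths.

# Degree by explicit double loop over the adjacency rule.
oracle_degrees <- function(r, threshold, excluded = NULL) {
  n <- nrow(r)
  if (is.null(excluded)) excluded <- matrix(FALSE, n, n)
  deg <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && !excluded[i, j] && r[i, j] >= threshold)
        deg[i] <- deg[i] + 1L
    }
  }
  deg
}

# FCS by explicit per-node summation.
oracle_fcs <- function(r, r0, excluded = NULL) {
  n <- nrow(r)
  if (is.null(excluded)) excluded <- matrix(FALSE, n, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (i != j && !excluded[i, j] && r[i, j] > r0)
        s <- s + atanh(min(r[i, j], 1 - 1e-12))
    }
    out[i] <- s / n
  }
  out
}

# Pairwise distance-exclusion set by explicit scan.
oracle_excluded_pairs <- function(coords, d_min) {
  n <- nrow(coords)
  excl <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && sqrt(sum((coords[i, ] - coords[j, ])^2)) < d_min)
        excl[i, j] <- TRUE
    }
  }
  excl
}

# Pairwise Pearson correlation from the textbook formula.
oracle_correlation <- function(series) {
  n <- nrow(series)
  r <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        xi <- series[i, ]; xj <- series[j, ]
        r[i, j] <- sum((xi - mean(xi)) * (xj - mean(xj))) /
          sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
      }
    }
  }
  r
}

# Bin mass of the truncated power law by adaptive quadrature, bin by bin.
oracle_tpl_bin <- function(k, alpha, lam) {
  vapply(k, function(kk)
    stats::integrate(function(t) t^(-alpha) * exp(-lam * t),
                     kk - 0.5, kk + 0.5, rel.tol = 1e-12)$value, 0)
}

# Continuous-approximation power-law log-likelihood (support [xmin - 1/2, inf)):
# the likelihood whose exact maximizer is the closed-form alpha-hat.
oracle_cont_pl_loglik <- function(alpha, x, xmin = 1) {
  x0 <- xmin - 0.5
  length(x) * log((alpha - 1) / x0) - alpha * sum(log(x / x0))
}

# Grid argmax of the continuous-approximation likelihood.
oracle_grid_alpha <- function(x, xmin = 1, grid = seq(1.001, 8, by = 1e-3)) {
  ll <- vapply(grid, oracle_cont_pl_loglik, 0, x = x, xmin = xmin)
  grid[which.max(ll)]
}

# Chi-square goodness of fit of a sample against a pmf table, greedily
# pooling adjacent bins so every expected count is >= 5 (mass beyond the
# table goes into the final bin).
gof_pvalue <- function(x, k, pmf) {
  n <- length(x)
  exp_full <- c(pmf, max(0, 1 - sum(pmf))) * n
  obs_full <- c(tabulate(factor(x, levels = k)), sum(!x %in% k))
  gid <- integer(length(exp_full))
  g <- 1L; acc <- 0
  for (i in seq_along(exp_full)) {
    gid[i] <- g
    acc <- acc + exp_full[i]
    if (acc >= 5) { g <- g + 1L; acc <- 0 }
  }
  if (acc > 0 && g > 1L) gid[gid == g] <- g - 1L  # fold trailing remainder
  E <- tapply(exp_full, gid, sum)
  O <- tapply(obs_full, gid, sum)
  stat <- sum((O - E)^2 / E)
  stats::pchisq(stat, df = length(E) - 1L, lower.tail = FALSE)
}

# Small random symmetric "correlation-like" matrix.
random_sym_r <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, -1, 1), n, n)
  r <- (m + t(m)) / 2
  diag(r) <- 1
  r
}

make_cohort_df <- function(n_hc, n_amci, seed = 1) {
  set.seed(seed)
  n <- n_hc + n_amci
  data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = factor(rep(c("HC", "aMCI"), c(n_hc, n_amci)),
                   levels = c("HC", "aMCI")),
    age = round(stats::rnorm(n, 72, 6), 1),
    gender = factor(sample(c("F", "M"), n, replace = TRUE)),
    education = round(pmax(stats::rnorm(n, 4.2, 1), 0), 1),
    mmse = round(stats::runif(n, 24, 30), 1),
    moca = round(stats::runif(n, 20, 28), 1))
}
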