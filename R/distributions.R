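#' Discrete heavy-tailed degree-distribution models
#'
#' Probability mass, log-mass and survival functions for the three candidate
#' degree-distribution models on integer support `k >= xmin`:
#'
#' * `"powerlaw"`: \eqn{P(k) = k^{-\alpha} / \zeta(\alpha, x_{min})}, the exact
#'   discrete (zeta-normalized) power law.
#' * `"truncated_powerlaw"` (power law with exponential cutoff): continuous
#'   density \eqn{f(x) \propto x^{-\alpha} e^{-\lambda x}}, discretized by
#'   rounding: \eqn{P(k) \propto \int_{k-1/2}^{k+1/2} f}.
#' * `"weibull"` (stretched exponential): continuous density
#'   \eqn{f(x) \propto x^{\beta-1} e^{-\lambda x^\beta}}, survival
#'   \eqn{S(x) = e^{-\lambda x^\beta}}, discretized by rounding.
#'
#' The rounding discretization assigns \eqn{P(k) = [S(k-1/2) - S(k+1/2)] /
#' S(x_{min}-1/2)}, so the pmf sums exactly to 1 over `k >= xmin` (the bins
#' telescope). The shape parameter of the Weibull interpolates between
#' power-law-like behaviour (\eqn{\beta \to 0}) and the exponential
#' (\eqn{\beta = 1}).
#'
#' @param model one of `"powerlaw"`, `"truncated_powerlaw"`, `"weibull"`.
#' @param params named numeric vector/list of parameters: `alpha` for the
#'   power law; `alpha`, `lambda` for the truncated power law; `beta`,
#'   `lambda` for the Weibull.
#' @param k integer value(s) `>= xmin` at which to evaluate.
#' @param xmin smallest value of the support (integer `>= 1`).
#' @return `discrete_pmf`: probabilities; `discrete_logpmf`: their logs;
#'   `discrete_survival`: \eqn{P(X \ge k)}.
#' @examples
#' discrete_pmf("weibull", c(beta = 1, lambda = 0.5), k = 1:5)
#' sum(discrete_pmf("powerlaw", c(alpha = 2.5), k = 1:10000))
#' @export
discrete_pmf <- function(model, params, k, xmin = 1L) {
  exp(discrete_logpmf(model, params, k, xmin))
}

#' @rdname discrete_pmf
#' @export
discrete_logpmf <- function(model, params, k, xmin = 1L) {
  check_model_params(model, params)
  stopifnot(xmin >= 1, all(k >= xmin), all(k == round(k)))
  p <- as.list(params)
  switch(model,
    powerlaw = {
      -p$alpha * log(k) - log(hurwitz_zeta(p$alpha, xmin))
    },
    weibull = {
      a <- p$lambda * (k - 0.5)^p$beta
      b <- p$lambda * (k + 0.5)^p$beta
      log_exp_diff(a, b) + p$lambda * (xmin - 0.5)^p$beta
    },
    truncated_powerlaw = {
      tpl_log_bin(k, p$alpha, p$lambda) -
        tpl_log_survival(xmin - 0.5, p$alpha, p$lambda)
    }
  )
}

#' @rdname discrete_pmf
#' @export
discrete_survival <- function(model, params, k, xmin = 1L) {
  check_model_params(model, params)
  stopifnot(xmin >= 1, all(k >= xmin), all(k == round(k)))
  p <- as.list(params)
  switch(model,
    powerlaw = {
      vapply(k, function(kk) hurwitz_zeta(p$alpha, kk), 0) /
        hurwitz_zeta(p$alpha, xmin)
    },
    weibull = {
      exp(-p$lambda * (k - 0.5)^p$beta + p$lambda * (xmin - 0.5)^p$beta)
    },
    truncated_powerlaw = {
      s0 <- tpl_log_survival(xmin - 0.5, p$alpha, p$lambda)
      exp(vapply(k - 0.5, tpl_log_survival, 0,
                 alpha = p$alpha, lam = p$lambda) - s0)
    }
  )
}

check_model_params <- function(model, params) {
  models <- c("powerlaw", "truncated_powerlaw", "weibull")
  if (!is.character(model) || length(model) != 1L || !model %in% models)
    stop("`model` must be one of: ", paste(models, collapse = ", "))
  p <- as.list(params)
  bad <- function(msg) stop("invalid parameters for ", model, ": ", msg)
  if (model == "powerlaw") {
    if (is.null(p$alpha) || !is.finite(p$alpha)) bad("alpha missing")
    if (p$alpha <= 1) bad("alpha must exceed 1 (non-normalizable otherwise)")
  } else if (model == "truncated_powerlaw") {
    if (is.null(p$alpha) || is.null(p$lambda)) bad("need alpha and lambda")
    if (!is.finite(p$alpha) || !is.finite(p$lambda)) bad("non-finite")
    if (p$lambda <= 0) bad("lambda must be positive")
  } else {
    if (is.null(p$beta) || is.null(p$lambda)) bad("need beta and lambda")
    if (!is.finite(p$beta) || !is.finite(p$lambda)) bad("non-finite")
    if (p$beta <= 0 || p$lambda <= 0) bad("beta and lambda must be positive")
  }
  invisible(TRUE)
}

# --- truncated power law numerics -------------------------------------------
# Bin mass integral log int_{k-1/2}^{k+1/2} t^-alpha e^(-lambda t) dt by
# 10-node Gauss-Legendre per unit bin; the integrand is smooth on a unit
# interval so this is accurate to near machine precision.
tpl_gl_cache <- new.env(parent = emptyenv())
tpl_gl <- function() {
  if (is.null(tpl_gl_cache$v)) tpl_gl_cache$v <- gauss_legendre(10L)
  tpl_gl_cache$v
}

tpl_log_bin <- function(k, alpha, lam) {
  gl <- tpl_gl()
  nodes <- gl$nodes
  # t: length(k) x 10 matrix of quadrature points
  t <- outer(k, 0.5 * nodes, `+`)
  logf <- -alpha * log(t) - lam * t
  logw <- log(0.5 * gl$weights)
  logsumexp(sweep(logf, 2L, logw, `+`))
}

# log int_{x0}^infty t^-alpha e^(-lambda t) dt, computed as
# -lambda*x0 + log int_0^infty (x0+u)^-alpha e^(-lambda u) du for stability.
tpl_log_survival <- function(x0, alpha, lam) {
  stopifnot(x0 > 0)
  val <- stats::integrate(function(u) (x0 + u)^(-alpha) * exp(-lam * u),
                          lower = 0, upper = Inf,
                          rel.tol = 1e-10, abs.tol = 0)$value
  -lam * x0 + log(val)
}

# pmf lookup table for sampling: values xmin..K where the cumulative mass
# first exceeds 1 - tail_mass (bounded by max_len rows).
pmf_table <- function(model, params, xmin = 1L, tail_mass = 1e-9,
                      max_len = 5e6) {
  check_model_params(model, params)
  k_hi <- pmf_support_cap(model, params, xmin, tail_mass)
  if (k_hi - xmin + 1 > max_len)
    stop("pmf table would need more than ", max_len, " rows; ",
         "parameters give too heavy a tail for table-based sampling")
  k <- xmin:k_hi
  pmf <- discrete_pmf(model, params, k, xmin)
  list(k = k, pmf = pmf, mass = sum(pmf))
}

# Smallest K with P(X > K) <= tail_mass, by doubling + bisection on the
# survival function.
pmf_support_cap <- function(model, params, xmin, tail_mass) {
  surv <- function(k) discrete_survival(model, params, k, xmin)
  hi <- xmin + 1
  while (surv(hi + 1) > tail_mass) {
    hi <- hi * 2
    if (hi > 2^40) stop("support cap search exceeded 2^40")
  }
  lo <- xmin
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (surv(mid + 1) > tail_mass) lo <- mid else hi <- mid
  }
  hi
}
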