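test_that("ccdf counts proportions at or above each value", {
  expect_equal(ccdf(c(1, 1, 2, 3)),
               data.frame(value = c(1, 2, 3), proportion = c(1, 0.5, 0.25)))
  expect_equal(ccdf(rep(4L, 9)), data.frame(value = 4L, proportion = 1))
  expect_error(ccdf(integer(0)), "empty")
  set.seed(1)
  x <- sample(1:20, 500, replace = TRUE)
  tab <- ccdf(x)
  v <- sort(unique(x))
  expect_equal(tab$value, v)
  expect_equal(tab$proportion, sapply(v, function(a) sum(x >= a)) / 500)
  expect_true(all(diff(tab$proportion) <= 0))
  expect_equal(tab$proportion[1], 1)
})

test_that("closed-form power-law estimate equals the printed formula", {
  expect_equal(unname(fit_powerlaw_discrete(rep(1L, 50))$params["alpha"]),
               1 + 1 / log(2), tolerance = 1e-12)
  x <- c(1L, 2L, 4L, 8L)
  expect_equal(unname(fit_powerlaw_discrete(x)$params["alpha"]),
               1 + 4 / sum(log(x / 0.5)), tolerance = 1e-12)
  expect_error(fit_powerlaw_discrete(c(1L, 5L), xmin = 2L), ">= xmin")
})

test_that("closed form maximizes its continuous-approximation likelihood (grid)", {
  for (s in 1:10) {
    x <- sample_discrete_weibull(400, beta = runif(1, 0.4, 1.2),
                                 lambda = runif(1, 0.05, 0.4),
                                 seed = 700 + s)
    ahat <- unname(fit_powerlaw_discrete(x)$params["alpha"])
    expect_lt(abs(ahat - oracle_grid_alpha(x)), 1e-2)
  }
})

test_that("exact discrete MLE recovers the exponent of zeta-sampled data", {
  x <- sample_discrete_powerlaw(1e4, alpha = 2.5, seed = 31)
  f <- fit_powerlaw_discrete(x)
  expect_gt(f$alpha_exact, 2.4)
  expect_lt(f$alpha_exact, 2.6)
  # the exact MLE and the generic fitter agree
  f2 <- fit_discrete_mle(x, "powerlaw")
  expect_equal(unname(f2$params["alpha"]), f$alpha_exact, tolerance = 1e-6)
})

test_that("xmin selection minimizes the KS distance and keeps ties small", {
  x <- sample_discrete_powerlaw(500, alpha = 2.2, seed = 41)
  sel <- select_xmin_ks(x)
  # exhaustive re-scan agrees with the operation's choice
  ks_all <- vapply(sort(unique(x)), function(xm) {
    xs <- x[x >= xm]
    if (length(xs) < 2) return(NA_real_)
    fit_powerlaw_discrete(xs, xmin = xm)$ks_distance
  }, 0)
  expect_equal(sel$ks_distance, min(ks_all, na.rm = TRUE))
  cand <- sort(unique(x))[!is.na(ks_all)]
  expect_equal(sel$xmin, cand[which.min(ks_all[!is.na(ks_all)])])
  # no candidate below the sample minimum
  y <- sample_discrete_powerlaw(200, alpha = 2.5, xmin = 5L, seed = 42)
  expect_true(all(select_xmin_ks(y)$scan$xmin >= 5))
  # pure power-law samples select a small xmin most of the time
  hits <- sum(vapply(1:10, function(s) {
    z <- sample_discrete_powerlaw(1000, alpha = 2.5, seed = 800 + s)
    select_xmin_ks(z)$xmin <= 3
  }, NA))
  expect_gte(hits, 9)
})

test_that("Weibull MLE recovers parameters, including the exponential boundary", {
  x <- sample_discrete_weibull(5000, beta = 1, lambda = 0.2, seed = 51)
  f <- fit_discrete_mle(x, "weibull")
  expect_gt(unname(f$params["beta"]), 0.9)
  expect_lt(unname(f$params["beta"]), 1.1)
  expect_true(f$converged)
  expect_true(is.finite(f$loglik))
})

test_that("truncated power-law MLE recovers its parameters", {
  x <- sample_discrete_tpl(5000, alpha = 2, lambda = 0.1, seed = 52)
  f <- fit_discrete_mle(x, "truncated_powerlaw")
  expect_lt(abs(unname(f$params["alpha"]) - 2), 0.15)
  expect_lt(abs(unname(f$params["lambda"]) - 0.1), 0.05)
})

test_that("optimum is never beaten by a parameter grid", {
  for (cfg in list(list("weibull", function(s) sample_discrete_weibull(
                     800, 0.6, 0.15, seed = s)),
                   list("truncated_powerlaw", function(s) sample_discrete_tpl(
                     800, 1.8, 0.12, seed = s)))) {
    model <- cfg[[1]]
    for (s in c(61, 62, 63, 64, 65)) {
      x <- cfg[[2]](s)
      f <- fit_discrete_mle(x, model)
      tab <- table(x)
      k <- as.integer(names(tab)); cnt <- as.integer(tab)
      box <- weibullnet:::param_box(model)
      g1 <- seq(box$lower[1], box$upper[1], length.out = 50)
      g2 <- exp(seq(log(box$lower[2] + 1e-8), log(box$upper[2]),
                    length.out = 50))
      grid_best <- -Inf
      for (a in g1) {
        ll <- vapply(g2, function(b) {
          p <- stats::setNames(c(a, b), weibullnet:::param_names(model))
          sum(cnt * discrete_logpmf(model, p, k))
        }, 0)
        grid_best <- max(grid_best, max(ll))
      }
      expect_gte(f$loglik, grid_best - 1e-3)
    }
  }
})

test_that("fitted Weibull CCDF lies between matched power law and exponential", {
  params <- c(beta = 0.5, lambda = 0.3)
  tab <- weibullnet:::pmf_table("weibull", params, 1L)
  mu <- sum(tab$k * tab$pmf) / tab$mass
  # match first moments: exponential-type (shape 1) and discrete power law
  lam_e <- stats::uniroot(function(l) {
    t2 <- weibullnet:::pmf_table("weibull", c(beta = 1, lambda = l), 1L)
    sum(t2$k * t2$pmf) / t2$mass - mu
  }, c(0.01, 5))$root
  hz <- weibullnet:::hurwitz_zeta
  alpha_m <- stats::uniroot(function(a) hz(a - 1, 1) / hz(a, 1) - mu,
                            c(2.001, 6))$root
  # far enough out that the moment-matched power law (alpha near 2, hence
  # bulk-heavy) has overtaken the stretched-exponential tail
  k_far <- ceiling(50 * mu)
  s_w <- discrete_survival("weibull", params, k_far)
  s_e <- discrete_survival("weibull", c(beta = 1, lambda = lam_e), k_far)
  s_p <- discrete_survival("powerlaw", c(alpha = alpha_m), k_far)
  expect_gt(s_w, s_e)
  expect_gt(s_p, s_w)
})
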