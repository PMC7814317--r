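test_that("samplers are deterministic under a seed and respect the support", {
  a <- sample_discrete_weibull(500, beta = 0.5, lambda = 0.1, seed = 7)
  b <- sample_discrete_weibull(500, beta = 0.5, lambda = 0.1, seed = 7)
  expect_identical(a, b)
  p <- sample_discrete_powerlaw(500, alpha = 2.5, xmin = 3L, seed = 7)
  expect_true(all(p >= 3))
  expect_identical(p, sample_discrete_powerlaw(500, alpha = 2.5, xmin = 3L,
                                               seed = 7))
  expect_length(sample_discrete_powerlaw(1, alpha = 2.5, seed = 1), 1L)
  t1 <- sample_discrete_tpl(500, alpha = 2, lambda = 0.1, seed = 7)
  expect_identical(t1, sample_discrete_tpl(500, alpha = 2, lambda = 0.1,
                                           seed = 7))
  expect_error(sample_discrete_weibull(0, 0.5, 0.1), "n must be >= 1")
  expect_error(sample_discrete_weibull(5, -0.5, 0.1), "positive")
  expect_error(sample_discrete_powerlaw(5, alpha = 0.9), "alpha")
})

test_that("degenerate parameters collapse the samples onto xmin", {
  x <- sample_discrete_weibull(200, beta = 1, lambda = 20, seed = 1)
  expect_true(all(x == 1L))
  y <- sample_discrete_powerlaw(5000, alpha = 10, seed = 2)
  expect_gte(mean(y == 1L), 0.99)  # pmf(1) = 1/zeta(10) = 0.999
})

test_that("sampled frequencies match the fitting module's pmf (chi-square GOF)", {
  n <- 1e5
  cases <- list(
    list(sample_discrete_weibull(n, 0.5, 0.1, seed = 11),
         "weibull", c(beta = 0.5, lambda = 0.1)),
    list(sample_discrete_powerlaw(n, 2.5, seed = 12),
         "powerlaw", c(alpha = 2.5)),
    list(sample_discrete_tpl(n, 2, 0.1, seed = 13),
         "truncated_powerlaw", c(alpha = 2, lambda = 0.1)))
  for (cs in cases) {
    k <- 1:max(cs[[1]])
    pmf <- discrete_pmf(cs[[2]], cs[[3]], k)
    expect_gt(gof_pvalue(cs[[1]], k, pmf), 0.001, label = cs[[2]])
  }
})

test_that("power-law sample mean matches the analytic zeta mean", {
  # alpha = 3.5 keeps the variance finite so the 3-SE band is meaningful
  n <- 1e4
  x <- sample_discrete_powerlaw(n, alpha = 3.5, seed = 21)
  hz <- weibullnet:::hurwitz_zeta
  mu <- hz(2.5, 1) / hz(3.5, 1)
  v <- hz(1.5, 1) / hz(3.5, 1) - mu^2
  expect_lt(abs(mean(x) - mu), 3 * sqrt(v / n))
})

test_that("synthetic scenes honour point-mass hubness limits", {
  sc0 <- generate_timeseries(60, 120, hubness = 0, seed = 3)
  g0 <- correlation_matrix(sc0)
  expect_lt(max(abs(g0$r[upper.tri(g0$r)])), 0.5)
  expect_true(all(compute_degrees(g0, 0.5) == 0))

  sc1 <- generate_timeseries(60, 120, hubness = 1, n_communities = 1, seed = 3)
  g1 <- correlation_matrix(sc1)
  expect_true(all(g1$r > 0.999))
  expect_true(all(compute_degrees(g1, 0.4) == 59L))

  expect_equal(dim(sc0$coords), c(60L, 3L))
  expect_false(any(duplicated(sc0$coords)))
  expect_equal(sort(unique(diff(sort(unique(sc0$coords[, 1]))))), 3)
})

test_that("scene degree sequences favour the Weibull over the power law", {
  wins <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    sc <- generate_timeseries(400, 150, seed = 100 + s)
    g <- apply_distance_exclusion(correlation_matrix(sc), d_min = 20)
    deg <- compute_degrees(g, 0.4)
    x <- deg[deg >= 1]
    fw <- fit_discrete_mle(x, "weibull")
    fp <- fit_discrete_mle(x, "powerlaw")
    cm <- compare_models(x, fw, fp)
    if (cm$R > 0 && cm$p < 0.05) wins <- wins + 1L
  }
  expect_gte(wins / n_seeds, 0.9)
})

test_that("cohorts are reproducible, valid, and carry the injected effect", {
  c1 <- generate_cohort(8, 8, delta_beta = 0.15, seed = 5)
  c2 <- generate_cohort(8, 8, delta_beta = 0.15, seed = 5)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$degrees$degrees, c2$degrees$degrees)
  s <- c1$subjects
  expect_true(all(s$mmse >= 0 & s$mmse <= 30))
  expect_true(all(s$moca >= 0 & s$moca <= 30))
  expect_setequal(levels(s$group), c("HC", "aMCI"))
  expect_equal(cognitive_ability(s), (s$mmse + s$moca) / 2)
  bt <- c1$ground_truth$beta_true
  expect_lt(mean(bt[s$group == "aMCI"]), mean(bt[s$group == "HC"]))
  # 8 networks per subject
  expect_equal(nrow(c1$degrees), 16 * 8)
})

test_that("stronger injected effects yield smaller group-difference p-values", {
  mean_p <- vapply(c(0, 0.08, 0.2), function(delta) {
    ps <- vapply(1:6, function(rep) {
      co <- generate_cohort(10, 10, delta_beta = delta, n_deg = 500L,
                            seed = 9000 + rep + round(1000 * delta))
      wb <- co$degrees[co$degrees$network == "whole_brain", ]
      bhat <- vapply(wb$degrees, function(x)
        unname(fit_discrete_mle(x[x >= 1], "weibull")$params["beta"]), 0)
      stats::t.test(bhat[co$subjects$group == "HC"],
                    bhat[co$subjects$group == "aMCI"])$p.value
    }, 0)
    mean(ps)
  }, 0)
  expect_true(all(diff(mean_p) < 0))
})
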