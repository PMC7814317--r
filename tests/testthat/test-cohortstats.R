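test_that("2x2 chi-square reproduces the printed gender comparison", {
  res <- chi2_2x2(rbind(c(28, 13), c(17, 13)))
  expect_equal(round(res$p, 2), 0.45)
  ident <- chi2_2x2(rbind(c(10, 10), c(10, 10)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)
  expect_error(chi2_2x2(rbind(c(0, 0), c(5, 5))), "margin")
  # textbook Yates formula, hand-evaluated, on random tables
  set.seed(5)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 15) + 1, 2, 2)
    n <- sum(tab)
    E <- outer(rowSums(tab), colSums(tab)) / n
    stat <- sum(pmax(abs(tab - E) - 0.5, 0)^2 / E)
    res <- suppressWarnings(chi2_2x2(tab))
    expect_equal(res$statistic, stat, tolerance = 1e-10)
    expect_equal(res$p, stats::pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("pooled t-test reproduces the printed cognitive comparisons", {
  mmse <- two_sample_t(summary_x = c(mean = 28.5, sd = 1.3, n = 41),
                       summary_y = c(mean = 26.7, sd = 1.9, n = 30))
  moca <- two_sample_t(summary_x = c(mean = 25.7, sd = 2.8, n = 41),
                       summary_y = c(mean = 22.2, sd = 3.5, n = 30))
  expect_lt(mmse$p, 0.001)
  expect_lt(moca$p, 0.001)
  same <- two_sample_t(summary_x = c(mean = 5, sd = 1, n = 10),
                       summary_y = c(mean = 5, sd = 1, n = 10))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # raw-vector path equals the summary path
  set.seed(6)
  x <- rnorm(20, 10, 2); y <- rnorm(15, 9, 2)
  raw <- two_sample_t(x, y)
  summ <- two_sample_t(summary_x = c(mean = mean(x), sd = sd(x), n = 20),
                       summary_y = c(mean = mean(y), sd = sd(y), n = 15))
  expect_equal(raw$t, summ$t)
  expect_equal(raw$p, summ$p)
  expect_equal(raw$t, unname(stats::t.test(x, y, var.equal = TRUE)$statistic))
  expect_error(two_sample_t(x, y[1]), "at least 2")
})

test_that("group-difference GLM matches the normal equations", {
  co <- make_cohort_df(12, 12)
  set.seed(7)
  param <- rnorm(24, 0.6, 0.05)
  res <- glm_group_difference(param, co)
  X <- cbind(1, as.numeric(co$group == "aMCI"), co$age,
             as.numeric(co$gender == "M"), co$education)
  beta <- solve(t(X) %*% X, t(X) %*% param)
  expect_equal(res$estimate, as.vector(beta), tolerance = 1e-9)
  # identical parameter values: zero group effect, zero residuals
  res0 <- suppressWarnings(glm_group_difference(rep(0.5, 24), co))
  expect_equal(res0$estimate[res0$term == "diagnosis"], 0)
  few <- c(1:3, 13:16)  # 3 HC, 4 aMCI
  expect_error(glm_group_difference(param[few], co[few, ]), "5 subjects")
})

test_that("cognition GLM interpolates exactly without noise and matches lm", {
  co <- make_cohort_df(0, 14)[, ]
  co$group <- factor(rep("aMCI", 14), levels = c("HC", "aMCI"))
  set.seed(8)
  param <- rnorm(14, 0.6, 0.08)
  cog_exact <- 3 + 25 * param
  res <- suppressWarnings(glm_cognition(cog_exact, param, co))
  expect_equal(res$estimate[res$term == "param"], 25, tolerance = 1e-8)
  cog <- cog_exact + rnorm(14, 0, 0.5) + 0.1 * co$age
  res2 <- res_lm <- summary(stats::lm(
    cog ~ param + age + gender + education,
    data = transform(co, gender = as.numeric(gender == "M"))))$coefficients
  ours <- glm_cognition(cog, param, co)
  expect_equal(ours$estimate, unname(res_lm[, 1]), tolerance = 1e-10)
  expect_equal(ours$t, unname(res_lm[, 3]), tolerance = 1e-10)
})

test_that("interaction model recovers group-specific slopes", {
  co <- make_cohort_df(15, 15)
  set.seed(9)
  param <- rnorm(30, 0.6, 0.1)
  is_amci <- co$group == "aMCI"
  # slopes +5 vs -5, low noise
  cog <- 20 + ifelse(is_amci, -5, 5) * param + rnorm(30, 0, 0.2)
  res <- interaction_model(cog, param, co)
  inter <- res[res$term == "diagnosis:param", ]
  expect_lt(inter$p_raw, 0.05)
  expect_lt(inter$estimate, 0)
  # the interaction column is the product of its factors
  mm <- stats::model.matrix(~ diagnosis * param,
                            data.frame(diagnosis = as.numeric(is_amci),
                                       param = param))
  expect_equal(mm[, "diagnosis:param"], as.numeric(is_amci) * param,
               ignore_attr = TRUE)
})

test_that("interaction p-values are calibrated under equal slopes", {
  ps <- vapply(1:40, function(s) {
    co <- generate_cohort(12, 12, delta_beta = 0, cognition_slope = 10,
                          n_deg = 50L, seed = 4000 + s)
    bt <- co$ground_truth$beta_true
    res <- interaction_model(cognitive_ability(co$subjects), unname(bt),
                             co$subjects)
    res$p_raw[res$term == "diagnosis:param"]
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH adjustment follows the step-up rule and its invariants", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(10)
  for (i in 1:10) {
    p <- runif(20)
    adj <- bh_fdr(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(adj, stats::p.adjust(p, "BH"))
    # monotone non-decreasing after sorting by raw p
    expect_false(is.unsorted(adj[order(p)]))
  }
})

test_that("voxelwise FCS map equals looping the GLM over voxels", {
  co <- make_cohort_df(10, 10)
  set.seed(11)
  fcs <- matrix(rnorm(20 * 30, 0.3, 0.05), 20, 30)
  fcs[co$group == "aMCI", 7] <- fcs[co$group == "aMCI", 7] + 0.5
  res <- fcs_group_map(fcs, co)
  loop <- t(vapply(seq_len(30), function(v) {
    r <- glm_group_difference(fcs[, v], co)
    unlist(r[r$term == "diagnosis", c("estimate", "t", "p_raw")])
  }, c(estimate = 0, t = 0, p_raw = 0)))
  expect_equal(res$estimate, unname(loop[, 1]), tolerance = 1e-10)
  expect_equal(res$t, unname(loop[, 2]), tolerance = 1e-10)
  expect_equal(res$p_raw, unname(loop[, 3]), tolerance = 1e-10)
  expect_equal(res$p_fdr, bh_fdr(res$p_raw))
  expect_equal(which.min(res$p_raw), 7L)  # injected voxel
  # identical maps in both groups: all t = 0
  fcs_same <- matrix(rep(rnorm(30), each = 20), 20, 30)
  res0 <- fcs_group_map(fcs_same, co)
  expect_true(all(res0$t == 0))
  expect_error(fcs_group_map(fcs[1:5, ], co), "do not match")
})

test_that("GLM inference is invariant to subject order and covariate scaling", {
  co <- make_cohort_df(10, 10)
  set.seed(12)
  param <- rnorm(20, 0.6, 0.05)
  base <- glm_group_difference(param, co)
  perm <- sample(20)
  reord <- glm_group_difference(param[perm], co[perm, ])
  expect_equal(reord$t, base$t, tolerance = 1e-9)
  co2 <- co; co2$age <- (co$age - 70) / 10
  scaled <- glm_group_difference(param, co2)
  expect_equal(scaled$t[scaled$term == "diagnosis"],
               base$t[base$term == "diagnosis"], tolerance = 1e-9)
})

test_that("demographics table carries group summaries and tests", {
  co <- generate_cohort(20, 15, seed = 90)$subjects
  demo <- suppressWarnings(demographics_table(co))
  expect_setequal(demo$variable,
                  c("N", "gender (F/M)", "age", "education", "mmse", "moca"))
  expect_equal(demo$hc[demo$variable == "N"], "20")
  expect_true(all(demo$p[demo$variable != "N"] >= 0))
})
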