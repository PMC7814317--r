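#' Calibration harnesses for the synthetic pipeline
#'
#' Monte-Carlo harnesses that exercise the full chain — generator, fitting,
#' comparison, group statistics — under known ground truth and report the
#' rates a calibrated pipeline must reach: parameter-recovery error,
#' model-selection win rate, group-difference power, familywise null
#' behaviour under FDR, and sign recovery of the cognition association.
#' These back the package's self-checks and the reproduction script.
#'
#' @param n_seeds,n_reps number of Monte-Carlo replicates.
#' @param n sample size per replicate.
#' @param beta,lambda true Weibull parameters of the generator.
#' @param seed base seed; replicate `i` uses `seed * 1000 + i`.
#' @return `calibrate_weibull_recovery`: list with `mean_abs_err_beta`,
#'   `mean_abs_err_lambda`, `beta_hat`, `lambda_hat`.
#' @export
calibrate_weibull_recovery <- function(n_seeds = 20L, n = 10000L,
                                       beta = 0.5, lambda = 0.1, seed = 1L) {
  est <- vapply(seq_len(n_seeds), function(i) {
    x <- sample_discrete_weibull(n, beta, lambda, seed = seed * 1000 + i)
    fit_discrete_mle(x, "weibull")$params
  }, c(beta = 0, lambda = 0))
  list(mean_abs_err_beta = mean(abs(est["beta", ] - beta)),
       mean_abs_err_lambda = mean(abs(est["lambda", ] - lambda)),
       beta_hat = est["beta", ], lambda_hat = est["lambda", ])
}

#' @rdname calibrate_weibull_recovery
#' @return `calibrate_model_selection`: list with `win_rate` (fraction of
#'   replicates where the Weibull beats the power law with `R > 0`,
#'   `p < 0.05`) and the per-replicate `R` and `p`.
#' @export
calibrate_model_selection <- function(n_seeds = 100L, n = 5000L,
                                      beta = 0.5, lambda = 0.1, seed = 1L) {
  out <- vapply(seq_len(n_seeds), function(i) {
    x <- sample_discrete_weibull(n, beta, lambda, seed = seed * 1000 + i)
    cm <- compare_models(x, fit_discrete_mle(x, "weibull"),
                         fit_discrete_mle(x, "powerlaw"))
    c(cm$R, cm$p)
  }, c(0, 0))
  list(win_rate = mean(out[1, ] > 0 & out[2, ] < 0.05),
       R = out[1, ], p = out[2, ])
}

# Fit the whole-brain (or every) per-subject Weibull shape for one cohort.
fit_cohort_betas <- function(cohort, networks = "whole_brain", xmin = 1L) {
  dt <- cohort$degrees
  if (!identical(networks, "all")) dt <- dt[dt$network %in% networks, ]
  dt$value <- vapply(dt$degrees, function(x) {
    x <- x[x >= xmin]
    unname(fit_discrete_mle(x, "weibull", xmin)$params["beta"])
  }, 0)
  dt[c("subject_id", "network", "value")]
}

#' @rdname calibrate_weibull_recovery
#' @param delta_beta injected group difference in the true Weibull shape.
#' @param n_hc,n_amci cohort sizes per replicate.
#' @param networks `"whole_brain"` (power on the focal test) or `"all"`
#'   (8-network family with FDR, for null calibration).
#' @return `calibrate_group_difference`: list with `reject_rate` (fraction of
#'   replicates with diagnosis `p < 0.05` on the whole-brain GLM),
#'   `fdr_any_rate` (fraction with any network significant after FDR; only
#'   when `networks = "all"`), and the per-replicate p-values.
#' @export
calibrate_group_difference <- function(n_reps = 20L, delta_beta = 0.1,
                                       n_hc = 20L, n_amci = 20L,
                                       networks = "whole_brain", seed = 1L) {
  p_wb <- numeric(n_reps)
  any_fdr <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    co <- generate_cohort(n_hc, n_amci, delta_beta = delta_beta,
                          seed = seed * 1000 + i)
    pt <- fit_cohort_betas(co, networks)
    if (identical(networks, "all")) {
      tab <- degree_group_analysis(pt, co$subjects)
      p_wb[i] <- tab$p_raw[tab$network == "whole_brain"]
      any_fdr[i] <- any(tab$p_fdr < 0.05)
    } else {
      v <- pt$value[match(co$subjects$subject_id, pt$subject_id)]
      res <- glm_group_difference(v, co$subjects)
      p_wb[i] <- res$p_raw[res$term == "diagnosis"]
      any_fdr[i] <- NA
    }
  }
  list(reject_rate = mean(p_wb < 0.05), fdr_any_rate = mean(any_fdr),
       p_whole_brain = p_wb, any_fdr_significant = any_fdr)
}

#' @rdname calibrate_weibull_recovery
#' @param cognition_slope injected slope of cognitive ability on the true
#'   shape.
#' @return `calibrate_cognition_sign`: list with `positive_sign_rate`
#'   (fraction of replicates where the fitted cognition slope on the
#'   whole-brain shape is positive within the aMCI group) and the
#'   per-replicate estimates.
#' @export
calibrate_cognition_sign <- function(n_reps = 20L, cognition_slope = 25,
                                     n_hc = 15L, n_amci = 15L, seed = 1L) {
  est <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    co <- generate_cohort(n_hc, n_amci, cognition_slope = cognition_slope,
                          seed = seed * 1000 + i)
    amci <- co$subjects$group == "aMCI"
    sub <- co$degrees[co$degrees$network == "whole_brain", ]
    bhat <- vapply(sub$degrees, function(x)
      unname(fit_discrete_mle(x[x >= 1], "weibull")$params["beta"]), 0)
    bhat <- bhat[match(co$subjects$subject_id, sub$subject_id)]
    res <- glm_cognition(cognitive_ability(co$subjects)[amci], bhat[amci],
                         co$subjects[amci, ])
    est[i] <- res$estimate[res$term == "param"]
  }
  list(positive_sign_rate = mean(est > 0), slope_estimates = est)
}
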