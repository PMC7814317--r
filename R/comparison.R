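#' Vuong-style normalized loglikelihood ratio between two fitted models
#'
#' For two fitted models on the same data and support, the pointwise
#' log-likelihood differences \eqn{d_i = \log p_a(x_i) - \log p_b(x_i)} give
#' the normalized ratio \deqn{R = \frac{\sum_i d_i}{\sigma \sqrt{n}},}
#' with \eqn{\sigma} the standard deviation of the \eqn{d_i}. A positive `R`
#' favours `fit_a`, a negative one `fit_b`, and the two-sided normal tail
#' probability `p` says whether the observed sign could plausibly arise from
#' chance fluctuations when the models fit equally well. When the two pmfs
#' coincide on the sample (\eqn{\sigma = 0}) the comparison is degenerate and
#' `R = 0, p = 1` is returned with a flag.
#'
#' @param x the degree sequence both models were fitted to.
#' @param fit_a,fit_b `"degfit"` objects fitted on `x` with the same `xmin`.
#' @return a `"model_comparison"` list: `model_a`, `model_b`, `R`, `sigma`,
#'   `p`, `n`, `degenerate`.
#' @export
compare_models <- function(x, fit_a, fit_b) {
  stopifnot(inherits(fit_a, "degfit"), inherits(fit_b, "degfit"))
  if (fit_a$xmin != fit_b$xmin)
    stop("fits use different xmin values")
  if (fit_a$n != length(x) || fit_b$n != length(x))
    stop("fits were not computed on this sample")
  d <- discrete_logpmf(fit_a$model, fit_a$params, x, fit_a$xmin) -
    discrete_logpmf(fit_b$model, fit_b$params, x, fit_b$xmin)
  n <- length(x)
  sigma <- sqrt(mean((d - mean(d))^2))
  if (sigma < 1e-12) {
    return(structure(list(model_a = fit_a$model, model_b = fit_b$model,
                          R = 0, sigma = 0, p = 1, n = n, degenerate = TRUE),
                     class = "model_comparison"))
  }
  R <- sum(d) / (sigma * sqrt(n))
  p <- 2 * stats::pnorm(-abs(R))
  structure(list(model_a = fit_a$model, model_b = fit_b$model,
                 R = R, sigma = sigma, p = p, n = n, degenerate = FALSE),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: R = %.4g, p = %.3g (n = %d)%s\n",
              x$model_a, x$model_b, x$R, x$p, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Fit all candidate models to every subject's degree sequences
#'
#' For each row of `degree_table` (one degree sequence per subject x network,
#' optionally x threshold) this fits the three candidate models by maximum
#' likelihood at `xmin` and computes the three pairwise normalized
#' loglikelihood ratios. Degrees of zero fall outside the support and are
#' dropped before fitting (their count is recorded per row).
#'
#' @param degree_table data.frame with columns `subject_id`, `network`,
#'   optionally `threshold`, and a list-column `degrees` (integer vectors);
#'   [generate_cohort()] returns this shape.
#' @param xmin lower support bound (default 1, the value used for model
#'   comparisons).
#' @return list with two data.frames: `fits` (one row per sequence x model,
#'   columns for the parameters, loglik, KS distance, convergence and the
#'   number of zero degrees dropped) and `comparisons` (one row per sequence
#'   x model pair, with `R` and `p`).
#' @seealso [group_mean_R()] for the group-level aggregation rule.
#' @export
fit_all_subjects <- function(degree_table, xmin = 1L) {
  stopifnot(is.data.frame(degree_table),
            all(c("subject_id", "network", "degrees") %in% names(degree_table)),
            nrow(degree_table) >= 1)
  has_thr <- "threshold" %in% names(degree_table)
  models <- c("weibull", "powerlaw", "truncated_powerlaw")
  pairs <- list(c("weibull", "powerlaw"),
                c("weibull", "truncated_powerlaw"),
                c("powerlaw", "truncated_powerlaw"))
  fits_rows <- list()
  cmp_rows <- list()
  for (i in seq_len(nrow(degree_table))) {
    x_all <- degree_table$degrees[[i]]
    x <- x_all[x_all >= xmin]
    n_dropped <- length(x_all) - length(x)
    key <- data.frame(subject_id = degree_table$subject_id[i],
                      network = degree_table$network[i],
                      stringsAsFactors = FALSE)
    if (has_thr) key$threshold <- degree_table$threshold[i]
    fits <- lapply(models, function(m) fit_discrete_mle(x, m, xmin))
    names(fits) <- models
    for (m in models) {
      f <- fits[[m]]
      fits_rows[[length(fits_rows) + 1L]] <- cbind(key, data.frame(
        model = m,
        param1 = unname(f$params[1]),
        param2 = if (length(f$params) > 1) unname(f$params[2]) else NA_real_,
        loglik = f$loglik, ks = f$ks_distance, n = f$n,
        n_zero_dropped = n_dropped, converged = f$converged,
        stringsAsFactors = FALSE))
    }
    for (pr in pairs) {
      cm <- compare_models(x, fits[[pr[1]]], fits[[pr[2]]])
      cmp_rows[[length(cmp_rows) + 1L]] <- cbind(key, data.frame(
        model_a = pr[1], model_b = pr[2], R = cm$R, p = cm$p, n = cm$n,
        stringsAsFactors = FALSE))
    }
  }
  list(fits = do.call(rbind, fits_rows),
       comparisons = do.call(rbind, cmp_rows))
}

#' Group-level mean of normalized loglikelihood ratios
#'
#' Aggregates per-subject model comparisons to the group level: within each
#' network (and threshold, if present) x model pair, the mean `R` is taken
#' over subjects whose comparison reached significance (`p < p_cut`); other
#' subjects contribute nothing. When no subject is significant the mean is
#' reported as `NA` with `n_significant = 0`.
#'
#' @param comparisons the `comparisons` data.frame from [fit_all_subjects()].
#' @param p_cut significance cutoff for inclusion (default 0.05).
#' @return data.frame with `network`, (`threshold`,) `model_a`, `model_b`,
#'   `mean_R`, `n_significant`, `n_total`.
#' @export
group_mean_R <- function(comparisons, p_cut = 0.05) {
  keys <- intersect(c("network", "threshold", "model_a", "model_b"),
                    names(comparisons))
  split_idx <- interaction(comparisons[keys], drop = TRUE)
  out <- do.call(rbind, lapply(split(comparisons, split_idx), function(g) {
    sig <- g$p < p_cut
    res <- g[1L, keys, drop = FALSE]
    res$mean_R <- if (any(sig)) mean(g$R[sig]) else NA_real_
    res$n_significant <- sum(sig)
    res$n_total <- nrow(g)
    res
  }))
  rownames(out) <- NULL
  out
}
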