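#' Two-tailed Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square with Yates continuity correction, degrees of freedom 1.
#' The continuity-corrected form is the one whose p-value reproduces the
#' printed gender comparison of the demographics table (28/13 vs 17/13 gives
#' p = 0.45; the uncorrected statistic would give 0.32).
#'
#' @param tab 2x2 matrix of non-negative counts with positive margins.
#' @param correct apply the Yates correction (default `TRUE`).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi2_2x2 <- function(tab, correct = TRUE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  ct <- stats::chisq.test(tab, correct = correct)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Two-sample two-tailed t-test (pooled variance)
#'
#' Classical pooled-variance t-test, accepting either raw per-group vectors
#' or `(mean, sd, n)` summaries — the latter lets printed summary tables be
#' tested directly. Welch's unequal-variance form is available via
#' `var_equal = FALSE` (raw vectors only).
#'
#' @param x,y raw numeric vectors, or `NULL` when summaries are given.
#' @param summary_x,summary_y optional `c(mean =, sd =, n =)` summaries.
#' @param var_equal pool the variances (default `TRUE`).
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
two_sample_t <- function(x = NULL, y = NULL,
                         summary_x = NULL, summary_y = NULL,
                         var_equal = TRUE) {
  summarize <- function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v))
  if (!is.null(x)) summary_x <- summarize(x)
  if (!is.null(y)) summary_y <- summarize(y)
  stopifnot(!is.null(summary_x), !is.null(summary_y))
  m1 <- summary_x[["mean"]]; s1 <- summary_x[["sd"]]; n1 <- summary_x[["n"]]
  m2 <- summary_y[["mean"]]; s2 <- summary_y[["sd"]]; n2 <- summary_y[["n"]]
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  if (s1 <= 0 && s2 <= 0) stop("both groups have zero variance")
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- s1^2 / n1 + s2^2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), mean_diff = m1 - m2)
}

# Design matrix used by all cohort GLMs: diagnosis coded HC = 0 / aMCI = 1,
# gender F = 0 / M = 1 (this coding makes a lower aMCI parameter appear as a
# negative diagnosis coefficient).
cohort_covariates <- function(cohort) {
  stopifnot(all(c("group", "age", "gender", "education") %in% names(cohort)))
  g <- as.character(cohort$group)
  if (!all(g %in% c("HC", "aMCI"))) stop("group labels must be HC / aMCI")
  sx <- as.character(cohort$gender)
  if (!all(sx %in% c("F", "M"))) stop("gender labels must be F / M")
  data.frame(diagnosis = as.numeric(g == "aMCI"),
             age = cohort$age,
             gender = as.numeric(sx == "M"),
             education = cohort$education)
}

lm_term_table <- function(fit, network = NA_character_) {
  sm <- summary(fit)$coefficients
  data.frame(network = network, term = rownames(sm),
             estimate = sm[, 1], t = sm[, 3], p_raw = sm[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group-difference GLM on a degree-model parameter
#'
#' Ordinary least squares of a per-subject model parameter on diagnosis with
#' age, gender and education as covariates:
#' `parameter ~ diagnosis + age + gender + education`. The diagnosis
#' coefficient (aMCI = 1) carries the group difference; a negative estimate
#' means the parameter is lower in aMCI.
#'
#' @param param per-subject parameter values (e.g. fitted Weibull shapes).
#' @param cohort subject table with `group`, `age`, `gender`, `education`.
#' @param network optional label recorded on the output.
#' @return data.frame with one row per model term: `network`, `term`,
#'   `estimate`, `t`, `p_raw`.
#' @export
glm_group_difference <- function(param, cohort, network = NA_character_) {
  X <- cohort_covariates(cohort)
  stopifnot(length(param) == nrow(X))
  if (min(table(X$diagnosis)) < 5)
    stop("need at least 5 subjects per group")
  d <- cbind(param = param, X)
  fit <- stats::lm(param ~ diagnosis + age + gender + education, data = d)
  if (fit$rank < 5) {
    alias <- colnames(stats::model.matrix(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(alias, collapse = ", "))
  }
  lm_term_table(fit, network)
}

#' Cognition regression on a degree-model parameter
#'
#' OLS of cognitive ability (mean of MMSE and MoCA) on a model parameter
#' with age, gender and education as covariates:
#' `cognition ~ parameter + age + gender + education`, run within a single
#' diagnostic group (the patient group, per the analysis design).
#'
#' @param cognition per-subject cognitive-ability scores.
#' @param param per-subject parameter values.
#' @param cohort subject table (already restricted to the group of interest).
#' @param network optional label recorded on the output.
#' @return data.frame with one row per term (`param` is the focal slope).
#' @export
glm_cognition <- function(cognition, param, cohort,
                          network = NA_character_) {
  stopifnot(length(cognition) == nrow(cohort),
            length(param) == nrow(cohort))
  d <- data.frame(cognition = cognition, param = param,
                  age = cohort$age,
                  gender = as.numeric(as.character(cohort$gender) == "M"),
                  education = cohort$education)
  fit <- stats::lm(cognition ~ param + age + gender + education, data = d)
  if (fit$rank < 5) {
    alias <- colnames(stats::model.matrix(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(alias, collapse = ", "))
  }
  lm_term_table(fit, network)
}

#' Diagnosis-by-parameter interaction on cognition
#'
#' Tests whether the slope of cognitive ability on the model parameter
#' differs between the diagnostic groups, controlling for age, gender and
#' education: `cognition ~ diagnosis * parameter + age + gender + education`.
#' The `diagnosis:param` row carries the interaction.
#'
#' @inheritParams glm_cognition
#' @param cohort full two-group subject table.
#' @return data.frame of model terms including `diagnosis:param`.
#' @export
interaction_model <- function(cognition, param, cohort,
                              network = NA_character_) {
  X <- cohort_covariates(cohort)
  stopifnot(length(cognition) == nrow(X), length(param) == nrow(X))
  if (length(unique(X$diagnosis)) < 2) stop("both groups must be present")
  d <- cbind(cognition = cognition, param = param, X)
  fit <- stats::lm(cognition ~ diagnosis * param + age + gender + education,
                   data = d)
  lm_term_table(fit, network)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate; adjusted
#' values never fall below the raw ones and are capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Demographics table with group tests
#'
#' Reproduces the usual cohort-characteristics table: per-group mean [SD]
#' for the continuous variables with pooled two-sample t-tests, and the
#' gender split with a Yates-corrected chi-square.
#'
#' @param cohort subject table.
#' @return data.frame with `variable`, `hc`, `amci`, `test`, `p`.
#' @export
demographics_table <- function(cohort) {
  hc <- cohort[cohort$group == "HC", ]
  mc <- cohort[cohort$group == "aMCI", ]
  fmt <- function(v) sprintf("%.1f [%.1f]", mean(v), stats::sd(v))
  cont <- c("age", "education", "mmse", "moca")
  rows <- lapply(cont, function(v) {
    tt <- two_sample_t(hc[[v]], mc[[v]])
    data.frame(variable = v, hc = fmt(hc[[v]]), amci = fmt(mc[[v]]),
               test = "pooled t", p = tt$p, stringsAsFactors = FALSE)
  })
  gtab <- rbind(table(factor(hc$gender, c("F", "M"))),
                table(factor(mc$gender, c("F", "M"))))
  gr <- data.frame(variable = "gender (F/M)",
                   hc = paste(gtab[1, ], collapse = "/"),
                   amci = paste(gtab[2, ], collapse = "/"),
                   test = "Yates chi-square", p = chi2_2x2(gtab)$p,
                   stringsAsFactors = FALSE)
  out <- rbind(data.frame(variable = "N", hc = nrow(hc), amci = nrow(mc),
                          test = "", p = NA, stringsAsFactors = FALSE),
               gr, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Voxelwise FCS group-difference map
#'
#' Fits the diagnosis + age + gender + education GLM at every voxel of a
#' subjects-by-voxels FCS matrix in one linear-algebra pass and FDR-corrects
#' the diagnosis p-values across voxels.
#'
#' @param fcs_mat numeric matrix, one row per subject, one column per voxel,
#'   rows aligned with `cohort`.
#' @param cohort subject table.
#' @return data.frame with `voxel`, `estimate`, `t`, `p_raw`, `p_fdr` for the
#'   diagnosis contrast.
#' @export
fcs_group_map <- function(fcs_mat, cohort) {
  fcs_mat <- as.matrix(fcs_mat)
  X <- cohort_covariates(cohort)
  if (nrow(fcs_mat) != nrow(X))
    stop("FCS matrix rows (", nrow(fcs_mat),
         ") do not match cohort size (", nrow(X), ")")
  Xm <- cbind(1, as.matrix(X))
  qr_x <- qr(Xm)
  if (qr_x$rank < ncol(Xm)) stop("rank-deficient design matrix")
  coefs <- qr.coef(qr_x, fcs_mat)               # p x n_voxels
  resid <- fcs_mat - Xm %*% coefs
  df <- nrow(Xm) - ncol(Xm)
  sigma2 <- colSums(resid^2) / df
  # residual variance at rounding-noise level means an exact fit: t := 0
  # rather than a ratio of floating-point residues
  scale <- colMeans(fcs_mat^2) + 1
  sigma2[sigma2 < 1e-20 * scale] <- 0
  xtx_inv <- chol2inv(qr.R(qr_x))
  j <- 2L                                       # diagnosis column
  se <- sqrt(sigma2 * xtx_inv[j, j])
  t <- ifelse(se > 0, coefs[j, ] / se, 0)
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(voxel = seq_len(ncol(fcs_mat)), estimate = coefs[j, ],
             t = t, p_raw = p, p_fdr = bh_fdr(p), row.names = NULL)
}

#' Per-network group-difference table with FDR across networks
#'
#' Runs [glm_group_difference()] for each network's per-subject parameter and
#' corrects the diagnosis p-values across the family of networks (whole brain
#' plus the seven subnetworks) with Benjamini-Hochberg. When several
#' thresholds are present each threshold's family is corrected separately.
#'
#' @param param_table data.frame with columns `subject_id`, `network`,
#'   optionally `threshold`, and `value` (the per-subject parameter).
#' @param cohort subject table.
#' @return data.frame with the diagnosis row per network: `network`,
#'   (`threshold`,) `estimate`, `t`, `p_raw`, `p_fdr`.
#' @export
degree_group_analysis <- function(param_table, cohort) {
  stopifnot(all(c("subject_id", "network", "value") %in% names(param_table)))
  has_thr <- "threshold" %in% names(param_table)
  fam <- if (has_thr) split(param_table, param_table$threshold)
         else list(param_table)
  out <- do.call(rbind, lapply(fam, function(ft) {
    rows <- do.call(rbind, lapply(split(ft, ft$network), function(g) {
      v <- g$value[match(cohort$subject_id, g$subject_id)]
      res <- glm_group_difference(v, cohort, network = g$network[1])
      res <- res[res$term == "diagnosis", ]
      if (has_thr) res$threshold <- g$threshold[1]
      res
    }))
    rows$p_fdr <- bh_fdr(rows$p_raw)
    rows
  }))
  rownames(out) <- NULL
  out
}
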