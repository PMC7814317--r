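#' Sample degree sequences from discrete heavy-tailed models
#'
#' Inverse-CDF samplers for the three candidate degree-distribution models,
#' drawing from exactly the same discretized pmfs that the fitting module
#' evaluates (see [discrete_pmf()]). The pmf is tabulated from `xmin` up to
#' the point where cumulative mass exceeds `1 - 1e-9` and renormalized; the
#' truncation bias is negligible at that mass.
#'
#' @param n number of draws (`>= 1`).
#' @param beta,alpha,lambda model parameters (all positive; `alpha > 1` for
#'   the pure power law).
#' @param xmin smallest attainable value (integer `>= 1`).
#' @param seed optional integer; when given, draws are reproducible and the
#'   caller's RNG state is left untouched.
#' @return integer vector of length `n`, all values `>= xmin`.
#' @examples
#' x <- sample_discrete_weibull(1000, beta = 0.5, lambda = 0.1, seed = 1)
#' range(x)
#' @export
sample_discrete_weibull <- function(n, beta, lambda, xmin = 1L, seed = NULL) {
  if (n < 1) stop("empty sample requested: n must be >= 1")
  check_model_params("weibull", c(beta = beta, lambda = lambda))
  stopifnot(xmin >= 1)
  # The discretized Weibull survival inverts in closed form:
  # P(X >= k) = exp(-lambda ((k-1/2)^beta - x0^beta)), x0 = xmin - 1/2, so
  # the inverse-CDF draw is k = max(xmin, ceiling(c - 1/2)) with
  # c = (x0^beta - log(1-u)/lambda)^(1/beta).
  x0b <- (xmin - 0.5)^beta
  with_seed(seed, {
    u <- stats::runif(n)
    cc <- (x0b - log1p(-u) / lambda)^(1 / beta)
    as.integer(pmax(xmin, ceiling(cc - 0.5)))
  })
}

#' @rdname sample_discrete_weibull
#' @export
sample_discrete_powerlaw <- function(n, alpha, xmin = 1L, seed = NULL) {
  if (n < 1) stop("empty sample requested: n must be >= 1")
  check_model_params("powerlaw", c(alpha = alpha))
  # Tabulate the head of the zeta pmf; draws landing beyond the table (the
  # extreme tail, which for small alpha cannot be tabulated to 1e-9 mass in
  # bounded memory) are inverted exactly by bisection on the survival
  # function.
  k_hi <- xmin + 99999L
  k <- xmin:k_hi
  pmf <- discrete_pmf("powerlaw", c(alpha = alpha), k, xmin)
  cum <- cumsum(pmf)
  zx <- hurwitz_zeta(alpha, xmin)
  with_seed(seed, {
    u <- stats::runif(n)
    idx <- findInterval(u, cum, left.open = TRUE) + 1L
    res <- integer(n)
    head_draw <- idx <= length(k)
    res[head_draw] <- k[idx[head_draw]]
    for (i in which(!head_draw)) {
      target <- (1 - u[i]) * zx         # want smallest m: zeta(alpha, m+1) <= target
      lo <- as.numeric(k_hi)
      hi <- 2 * lo
      while (hurwitz_zeta(alpha, hi + 1) > target) {
        lo <- hi
        hi <- 2 * hi
        if (hi > .Machine$integer.max)
          stop("tail draw exceeds integer range; alpha too close to 1")
      }
      while (hi - lo > 1) {
        mid <- floor((lo + hi) / 2)
        if (hurwitz_zeta(alpha, mid + 1) > target) lo <- mid else hi <- mid
      }
      res[i] <- as.integer(hi)
    }
    res
  })
}

#' @rdname sample_discrete_weibull
#' @export
sample_discrete_tpl <- function(n, alpha, lambda, xmin = 1L, seed = NULL) {
  if (n < 1) stop("empty sample requested: n must be >= 1")
  sample_from_table(
    pmf_table("truncated_powerlaw", c(alpha = alpha, lambda = lambda), xmin),
    n, seed)
}

sample_from_table <- function(tab, n, seed = NULL) {
  cum <- cumsum(tab$pmf) / tab$mass
  with_seed(seed, {
    u <- stats::runif(n)
    idx <- findInterval(u, cum, left.open = TRUE) + 1L
    as.integer(tab$k[pmin(idx, length(tab$k))])
  })
}

#' Simulate voxel time series with community structure and hubness
#'
#' Each voxel `i` carries a unit-variance mixture
#' \eqn{x_i(t) = \sqrt{c_i}\, s_{g(i)}(t) + \sqrt{1 - c_i}\,\epsilon_i(t)}
#' of a shared community signal \eqn{s_{g(i)}} (one per atlas label) and
#' private white noise. The coupling \eqn{c_i \in [0,1]} ("hubness") controls
#' how strongly a voxel correlates with its community: the population
#' correlation of two same-community voxels is \eqn{\sqrt{c_i c_j}}, so
#' high-hubness voxels become high-degree nodes once the correlation matrix
#' is thresholded. Voxel centers sit on a cubic lattice (default 3 mm
#' spacing) and atlas labels are assigned uniformly at random so that
#' communities are spatially interleaved rather than contiguous blobs.
#'
#' This stands in for cleaned, band-limited resting-state data; it makes no
#' attempt at hemodynamics, motion or scanner noise.
#'
#' @param n_voxels number of voxels (`>= 50`).
#' @param n_timepoints number of time points (`>= 100`).
#' @param hubness either a function `f(n)` returning `n` couplings in
#'   `[0, 1]`, or a single number for a point mass. Default `Beta(2, 5)`.
#' @param n_communities number of atlas labels (default 7).
#' @param grid_spacing lattice spacing in mm (default 3).
#' @param seed optional integer seed.
#' @return an object of class `"synthetic_scene"`: list with `series`
#'   (`n_voxels x n_timepoints`), `coords` (`n_voxels x 3`, mm), `atlas`
#'   (labels `1..n_communities`), `grid_spacing`, `hubness` (the realized
#'   couplings).
#' @export
generate_timeseries <- function(n_voxels, n_timepoints,
                                hubness = function(n) stats::rbeta(n, 2, 5),
                                n_communities = 7L, grid_spacing = 3,
                                seed = NULL) {
  stopifnot(n_voxels >= 50, n_timepoints >= 100, n_communities >= 1)
  if (is.numeric(hubness) && length(hubness) == 1L) {
    h0 <- hubness
    hubness <- function(n) rep(h0, n)
  }
  with_seed(seed, {
    c_i <- hubness(n_voxels)
    if (any(c_i < 0 | c_i > 1)) stop("hubness couplings must lie in [0, 1]")
    if (all(c_i == 0))
      message("degenerate hubness: all couplings zero; ",
              "expect an (almost) empty graph")
    atlas <- sample.int(n_communities, n_voxels, replace = TRUE)
    s <- matrix(stats::rnorm(n_communities * n_timepoints),
                n_communities, n_timepoints)
    eps <- matrix(stats::rnorm(n_voxels * n_timepoints),
                  n_voxels, n_timepoints)
    series <- sqrt(c_i) * s[atlas, , drop = FALSE] + sqrt(1 - c_i) * eps
    side <- ceiling(n_voxels^(1 / 3))
    g <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                               z = seq_len(side)))[seq_len(n_voxels), ,
                                                   drop = FALSE]
    coords <- g * grid_spacing
    structure(list(series = series, coords = coords, atlas = atlas,
                   grid_spacing = grid_spacing, hubness = c_i),
              class = "synthetic_scene")
  })
}

#' Generate a synthetic two-group cohort with known ground truth
#'
#' Builds a cohort of healthy controls (HC) and amnestic-MCI (aMCI) subjects
#' in which the whole-brain degree distribution of every subject is a
#' discrete Weibull with a subject-specific true shape \eqn{\beta_i}:
#' HC draw \eqn{\beta_i \sim N(\beta_{HC}, sd_\beta)} and aMCI
#' \eqn{\beta_i \sim N(\beta_{HC} - \Delta\beta, sd_\beta)}. Demographics
#' mirror the study design (aMCI older on average; similar education and
#' gender mix), and cognitive ability — the mean of MMSE and MoCA — is
#' linearly coupled to the subject's true \eqn{\beta_i} with Gaussian noise.
#'
#' Two generation modes:
#' * `"degrees"` (default): one whole-brain degree sequence per subject is
#'   sampled directly from the discrete Weibull, each node is assigned one of
#'   the 7 subnetwork labels uniformly, and the subnetwork sequences are the
#'   partition subsets — exactly the relation the graph module enforces
#'   (subnetwork degrees are global degrees restricted to member nodes).
#'   This gives exact distributional ground truth for recovery and power
#'   studies.
#' * `"timeseries"`: per-subject [generate_timeseries()] scenes in which the
#'   aMCI hubness distribution has more mass at high couplings (more hub
#'   nodes, hence a heavier-tailed degree distribution and lower fitted
#'   \eqn{\beta}); the shift scales with `delta_beta` but is qualitative,
#'   not calibrated.
#'
#' @param n_hc,n_amci group sizes (`>= 2`).
#' @param delta_beta true group difference in the Weibull shape (aMCI lower).
#' @param cognition_slope slope of cognitive ability on the true
#'   \eqn{\beta_i} (score points per unit shape).
#' @param beta_hc mean HC shape (default 0.65).
#' @param lambda Weibull rate parameter, common to all subjects.
#' @param sd_beta within-group SD of the true shape (default 0.05).
#' @param n_deg whole-brain degrees (nodes) per subject in `"degrees"` mode;
#'   each of the 7 subnetworks receives roughly `n_deg / 7` of them. The
#'   default 8000 keeps subnetwork fits precise, echoing voxel-level networks
#'   where even single subnetworks hold thousands of nodes.
#' @param cognition_sd SD of the cognition noise in score points.
#' @param age_slope age coefficient in the cognition model (points/year).
#' @param mode `"degrees"` or `"timeseries"`.
#' @param n_voxels,n_timepoints scene size for `"timeseries"` mode.
#' @param seed optional integer seed.
#' @return list with `subjects` (data.frame: subject_id, group, age, gender,
#'   education, mmse, moca), `degrees` (mode `"degrees"`: data.frame with one
#'   row per subject x network and a list-column `degrees`), `scenes` (mode
#'   `"timeseries"`: list of scenes), and `ground_truth` (true per-subject
#'   betas and all generator settings).
#' @export
generate_cohort <- function(n_hc, n_amci, delta_beta = 0.1,
                            cognition_slope = 25, beta_hc = 0.65,
                            lambda = 0.1, sd_beta = 0.05,
                            n_deg = 8000L,
                            cognition_sd = 1.5, age_slope = -0.05,
                            mode = c("degrees", "timeseries"),
                            n_voxels = 350L, n_timepoints = 150L,
                            seed = NULL) {
  stopifnot(n_hc >= 2, n_amci >= 2, lambda > 0, sd_beta >= 0,
            beta_hc - delta_beta > 0)
  mode <- match.arg(mode)
  networks <- c("whole_brain", "V", "SM", "DA", "VA", "Lim", "FP", "DM")
  with_seed(seed, {
    n <- n_hc + n_amci
    group <- factor(rep(c("HC", "aMCI"), c(n_hc, n_amci)),
                    levels = c("HC", "aMCI"))
    is_amci <- group == "aMCI"
    age <- ifelse(is_amci, stats::rnorm(n, 74.8, 5.7),
                  stats::rnorm(n, 70.3, 7.0))
    age <- pmin(pmax(age, 55), 85)
    gender <- factor(ifelse(stats::runif(n) <
                              ifelse(is_amci, 17 / 30, 28 / 41), "F", "M"),
                     levels = c("F", "M"))
    education <- pmax(stats::rnorm(n, ifelse(is_amci, 4.2, 4.3),
                                   ifelse(is_amci, 1.1, 0.9)), 0)
    beta_true <- stats::rnorm(n, beta_hc - delta_beta * is_amci, sd_beta)
    beta_true <- pmax(beta_true, 0.05)
    cog <- 27 + cognition_slope * (beta_true - beta_hc) +
      age_slope * (age - 72) + stats::rnorm(n, 0, cognition_sd)
    cog <- pmin(pmax(cog, 0), 30)
    spread <- stats::rnorm(n, 1.4, 0.5)
    mmse <- pmin(pmax(cog + spread, 0), 30)
    moca <- pmin(pmax(cog - spread, 0), 30)
    subjects <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = group, age = age, gender = gender, education = education,
      mmse = mmse, moca = moca, stringsAsFactors = FALSE)

    degrees <- NULL
    scenes <- NULL
    if (mode == "degrees") {
      rows <- expand.grid(subject_id = subjects$subject_id,
                          network = networks, stringsAsFactors = FALSE)
      rows <- rows[order(match(rows$subject_id, subjects$subject_id)), ]
      per_subject <- lapply(seq_len(n), function(i) {
        x <- sample_discrete_weibull(n_deg, beta = beta_true[i],
                                     lambda = lambda)
        lab <- sample.int(7L, n_deg, replace = TRUE)
        c(list(whole_brain = x),
          stats::setNames(lapply(1:7, function(k) x[lab == k]),
                          networks[-1]))
      })
      names(per_subject) <- subjects$subject_id
      rows$degrees <- lapply(seq_len(nrow(rows)), function(r)
        per_subject[[rows$subject_id[r]]][[rows$network[r]]])
      rownames(rows) <- NULL
      degrees <- rows
    } else {
      # aMCI hubness shifted toward high couplings: Beta(2, 5 - 10*delta)
      shift <- min(10 * delta_beta, 4)
      scenes <- lapply(seq_len(n), function(i) {
        b2 <- if (is_amci[i]) 5 - shift else 5
        generate_timeseries(n_voxels, n_timepoints,
                            hubness = function(m) stats::rbeta(m, 2, b2))
      })
    }

    ground_truth <- structure(list(
      model = "weibull", beta_hc = beta_hc, lambda = lambda,
      delta_beta = delta_beta, sd_beta = sd_beta,
      cognition_slope = cognition_slope, cognition_sd = cognition_sd,
      age_slope = age_slope, mode = mode, seed = seed,
      beta_true = stats::setNames(beta_true, subjects$subject_id)),
      class = "ground_truth")

    list(subjects = subjects, degrees = degrees, scenes = scenes,
         ground_truth = ground_truth)
  })
}

#' Cognitive ability score
#'
#' The mean of the MMSE and MoCA screening scores, the composite used as the
#' dependent variable of the cognition regression.
#'
#' @param subjects cohort data.frame with `mmse` and `moca` columns.
#' @return numeric vector in `[0, 30]`.
#' @export
cognitive_ability <- function(subjects) {
  stopifnot(all(c("mmse", "moca") %in% names(subjects)))
  (subjects$mmse + subjects$moca) / 2
}
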