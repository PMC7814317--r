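#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis with defaults set to the
#' study's printed values: correlation thresholds 0.4/0.5/0.6, FCS floor
#' `r0 = 0.2`, 20-mm distance exclusion, grey-matter cutoff 0.2, and
#' `xmin = 1` for model fitting and comparison.
#'
#' @param thresholds correlation thresholds (each in `(0, 1)`).
#' @param r0 FCS correlation floor.
#' @param d_min distance-exclusion radius, mm.
#' @param gm_cutoff grey-matter probability cutoff.
#' @param xmin lower support bound for degree-model fits.
#' @param n_hc,n_amci synthetic cohort sizes.
#' @param delta_beta,cognition_slope synthetic effect sizes.
#' @param n_deg whole-brain degrees per subject in `"degrees"` mode
#'   (subnetworks receive the partition subsets).
#' @param mode cohort generation mode (see [generate_cohort()]).
#' @param seed integer seed for the whole run.
#' @return a `"run_config"` list.
#' @export
run_config <- function(thresholds = c(0.4, 0.5, 0.6), r0 = 0.2, d_min = 20,
                       gm_cutoff = 0.2, xmin = 1L, n_hc = 10L, n_amci = 10L,
                       delta_beta = 0.1, cognition_slope = 25,
                       n_deg = 8000L,
                       mode = c("degrees", "timeseries"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(thresholds > 0 & thresholds < 1), r0 > 0, r0 < 1,
            d_min > 0, gm_cutoff >= 0, gm_cutoff <= 1, xmin >= 1)
  structure(list(thresholds = thresholds, r0 = r0, d_min = d_min,
                 gm_cutoff = gm_cutoff, xmin = as.integer(xmin),
                 n_hc = as.integer(n_hc), n_amci = as.integer(n_amci),
                 delta_beta = delta_beta, cognition_slope = cognition_slope,
                 n_deg = as.integer(n_deg),
                 mode = mode, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> (build networks) -> fit degree models -> compare -> group
#' statistics, writing every table into `out_dir`: the cohort CSV, per-row
#' degree TSVs, fit and comparison tables, the group-mean R table, the
#' group-difference and cognition GLM tables, CCDF tables for plotting, the
#' serialized configuration and ground truth, and a run log. Re-running with
#' the same configuration reproduces all numeric outputs.
#'
#' In `"degrees"` mode subject degree sequences come straight from the
#' generator's discrete Weibull ground truth; in `"timeseries"` mode scenes
#' are generated, correlation graphs built, the distance exclusion applied
#' and degrees computed at each configured threshold.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`cohort`, `fits`,
#'   `comparisons`, `group_R`, `group_diff`, `cognition`, `interaction`,
#'   `paths`).
#' @export
run_full_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("weibullnet %s | R %s | seed %d | mode %s",
       as.character(utils::packageVersion("weibullnet")),
       paste(R.version$major, R.version$minor, sep = "."),
       config$seed, config$mode)

  stage <- "simulate"
  res <- tryCatch({
    cohort <- generate_cohort(config$n_hc, config$n_amci,
                              delta_beta = config$delta_beta,
                              cognition_slope = config$cognition_slope,
                              n_deg = config$n_deg,
                              mode = config$mode, seed = config$seed)
    utils::write.csv(cohort$subjects,
                     file.path(out_dir, "cohort.csv"), row.names = FALSE)
    gt <- cohort$ground_truth
    jsonlite::write_json(gt[names(gt) != "beta_true"],
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "build"
    if (config$mode == "timeseries") {
      deg_rows <- list()
      for (i in seq_len(nrow(cohort$subjects))) {
        sc <- cohort$scenes[[i]]
        g <- correlation_matrix(sc)
        g <- apply_distance_exclusion(g, d_min = config$d_min)
        for (T in config$thresholds) {
          deg <- compute_degrees(g, T)
          deg_rows[[length(deg_rows) + 1L]] <- data.frame(
            subject_id = cohort$subjects$subject_id[i],
            network = "whole_brain", threshold = T, stringsAsFactors = FALSE)
          deg_rows[[length(deg_rows)]]$degrees <- list(deg)
          for (k in sort(unique(g$atlas))) {
            row <- data.frame(subject_id = cohort$subjects$subject_id[i],
                              network = paste0("net", k), threshold = T,
                              stringsAsFactors = FALSE)
            row$degrees <- list(subnetwork_degrees(deg, g$atlas, k))
            deg_rows[[length(deg_rows) + 1L]] <- row
          }
        }
      }
      degree_table <- do.call(rbind, deg_rows)
    } else {
      degree_table <- cohort$degrees
    }
    write_degree_tsv(degree_table, file.path(out_dir, "degrees.tsv"))

    stage <- "fit"
    fitted <- fit_all_subjects(degree_table, xmin = config$xmin)
    utils::write.table(fitted$fits, file.path(out_dir, "fits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    wb <- degree_table[degree_table$network == "whole_brain", ][1, ]
    ccdf_tab <- ccdf_with_fits(wb$degrees[[1]],
                               fitted$fits[fitted$fits$subject_id ==
                                             wb$subject_id &
                                           fitted$fits$network ==
                                             "whole_brain", ],
                               xmin = config$xmin)
    utils::write.table(ccdf_tab, file.path(out_dir, "ccdf_example.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    stage <- "compare"
    utils::write.table(fitted$comparisons,
                       file.path(out_dir, "comparisons.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    group_R <- group_mean_R(fitted$comparisons)
    utils::write.table(group_R, file.path(out_dir, "group_mean_R.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    stage <- "stats"
    wfit <- fitted$fits[fitted$fits$model == "weibull", ]
    param_table <- data.frame(subject_id = wfit$subject_id,
                              network = wfit$network, value = wfit$param1,
                              stringsAsFactors = FALSE)
    if ("threshold" %in% names(wfit)) param_table$threshold <- wfit$threshold
    group_diff <- degree_group_analysis(param_table, cohort$subjects)
    utils::write.table(group_diff, file.path(out_dir, "group_difference.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    amci <- cohort$subjects$group == "aMCI"
    cog <- cognitive_ability(cohort$subjects)
    nets <- unique(param_table$network)
    cog_rows <- do.call(rbind, lapply(nets, function(nw) {
      pt <- param_table[param_table$network == nw, ]
      if ("threshold" %in% names(pt)) pt <- pt[pt$threshold == pt$threshold[1], ]
      v <- pt$value[match(cohort$subjects$subject_id, pt$subject_id)]
      r <- glm_cognition(cog[amci], v[amci], cohort$subjects[amci, ],
                         network = nw)
      r[r$term == "param", ]
    }))
    cog_rows$p_fdr <- bh_fdr(cog_rows$p_raw)
    utils::write.table(cog_rows, file.path(out_dir, "cognition.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    inter <- do.call(rbind, lapply(nets, function(nw) {
      pt <- param_table[param_table$network == nw, ]
      if ("threshold" %in% names(pt)) pt <- pt[pt$threshold == pt$threshold[1], ]
      v <- pt$value[match(cohort$subjects$subject_id, pt$subject_id)]
      r <- interaction_model(cog, v, cohort$subjects, network = nw)
      r[r$term == "diagnosis:param", ]
    }))
    utils::write.table(inter, file.path(out_dir, "interaction.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    demo <- demographics_table(cohort$subjects)
    utils::write.table(demo, file.path(out_dir, "demographics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    cfg <- unclass(config)
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    logf("completed all stages")
    list(cohort = cohort, fits = fitted$fits,
         comparisons = fitted$comparisons, group_R = group_R,
         group_diff = group_diff, cognition = cog_rows,
         interaction = inter, demographics = demo,
         paths = list.files(out_dir, full.names = TRUE))
  }, error = function(e) {
    logf("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}

# Degree table (list-column) to a flat TSV: one row per sequence with degrees
# comma-joined; small cohorts only.
write_degree_tsv <- function(degree_table, path) {
  flat <- degree_table[setdiff(names(degree_table), "degrees")]
  flat$degrees <- vapply(degree_table$degrees, paste, "", collapse = ",")
  utils::write.table(flat, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

# CCDF of one sequence with the fitted model CCDFs alongside, for plotting.
ccdf_with_fits <- function(x, fits_rows, xmin = 1L) {
  x <- x[x >= xmin]
  tab <- ccdf(x)
  for (i in seq_len(nrow(fits_rows))) {
    m <- fits_rows$model[i]
    params <- stats::setNames(c(fits_rows$param1[i], fits_rows$param2[i]),
                              c(param_names(m), "pad")[seq_len(2)])
    params <- params[!is.na(params)]
    tab[[paste0("ccdf_", m)]] <-
      discrete_survival(m, params, tab$value, xmin)
  }
  tab
}

#' Read a NIfTI series/mask/atlas bundle into a scene
#'
#' Loads a 4D time-series volume, a grey-matter probability (or binary mask)
#' volume and an atlas label volume, checks that all three share the same
#' grid, applies the mask cutoff, and derives voxel center coordinates in mm
#' from the image affine.
#'
#' @param series_path path to the 4D NIfTI time series.
#' @param mask_path path to the 3D probability/mask volume.
#' @param atlas_path optional path to a 3D label volume (labels `0..7`,
#'   0 = unassigned).
#' @param gm_cutoff probability cutoff for the mask (default 0.2).
#' @return a `"synthetic_scene"`-shaped list restricted to mask voxels.
#' @export
read_nifti_bundle <- function(series_path, mask_path, atlas_path = NULL,
                              gm_cutoff = 0.2) {
  img <- RNifti::readNifti(series_path)
  msk <- RNifti::readNifti(mask_path)
  dims <- dim(img)
  if (length(dims) != 4L)
    stop("series must be 4D; got dims ", paste(dims, collapse = "x"))
  if (!all(dim(msk) == dims[1:3]))
    stop("mask grid ", paste(dim(msk), collapse = "x"),
         " does not match series grid ", paste(dims[1:3], collapse = "x"))
  atlas_img <- NULL
  if (!is.null(atlas_path)) {
    atlas_img <- RNifti::readNifti(atlas_path)
    if (!all(dim(atlas_img) == dims[1:3]))
      stop("atlas grid ", paste(dim(atlas_img), collapse = "x"),
           " does not match series grid ", paste(dims[1:3], collapse = "x"))
  }
  keep <- make_gm_mask(as.vector(msk), cutoff = gm_cutoff)
  nvox <- prod(dims[1:3])
  series <- matrix(as.vector(img), nrow = nvox)[keep, , drop = FALSE]
  ijk <- arrayInd(keep, dims[1:3]) - 1L  # 0-based voxel indices
  xf <- RNifti::xform(img)
  coords <- t(xf %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
  structure(list(series = series, coords = coords,
                 atlas = if (!is.null(atlas_img))
                   as.vector(atlas_img)[keep] else NULL,
                 grid_spacing = unname(RNifti::pixdim(img)[1]),
                 mask_index = keep),
            class = "synthetic_scene")
}

#' Write a scene to NIfTI volumes
#'
#' Inverse of [read_nifti_bundle()] for lattice scenes: places the series on
#' its bounding grid (unassigned cells zero), writes a 4D series volume, a
#' binary mask and the atlas labels, with the affine encoding the lattice
#' spacing in mm.
#'
#' @param scene a `"synthetic_scene"`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_scene_nifti <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- scene$grid_spacing
  ijk <- round(sweep(as.matrix(scene$coords), 2L, sp, `/`))
  ijk <- sweep(ijk, 2L, apply(ijk, 2L, min) - 1L)  # 1-based grid indices
  dims <- apply(ijk, 2L, max)
  nt <- ncol(scene$series)
  lin <- ijk[, 1] + dims[1] * (ijk[, 2] - 1L) + dims[1] * dims[2] * (ijk[, 3] - 1L)
  arr4 <- array(0, c(dims, nt))
  for (t in seq_len(nt)) arr4[lin + prod(dims) * (t - 1L)] <- scene$series[, t]
  mask <- array(0L, dims); mask[lin] <- 1L
  atl <- array(0L, dims)
  if (!is.null(scene$atlas)) atl[lin] <- scene$atlas
  paths <- file.path(dir, c("series.nii.gz", "mask.nii.gz", "atlas.nii.gz"))
  with_pixdim <- function(a, pd) {
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- pd
    img
  }
  RNifti::writeNifti(with_pixdim(arr4, c(rep(sp, 3), 1)), paths[1])
  RNifti::writeNifti(with_pixdim(mask, rep(sp, 3)), paths[2])
  RNifti::writeNifti(with_pixdim(atl, rep(sp, 3)), paths[3])
  invisible(paths)
}
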