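#' Grey-matter mask from a probability map
#'
#' Retains voxels whose grey-matter probability is at least `cutoff`
#' (inclusive boundary). The default cutoff 0.2 matches the value used when
#' thresholding a mean GM probability map to define the network's node set.
#'
#' @param prob_map numeric vector of per-voxel probabilities in `[0, 1]`.
#' @param cutoff retention threshold (default 0.2).
#' @return integer indices of retained voxels.
#' @export
make_gm_mask <- function(prob_map, cutoff = 0.2) {
  stopifnot(is.numeric(prob_map), all(prob_map >= 0 & prob_map <= 1))
  keep <- which(prob_map >= cutoff)
  if (length(keep) == 0L)
    stop("empty grey-matter mask: no voxel reaches the cutoff ", cutoff)
  keep
}

#' Voxelwise Pearson correlation graph
#'
#' Computes the full Pearson correlation matrix between the time series of
#' all pairs of eligible voxels. Voxels with zero temporal variance cannot
#' carry a correlation and are dropped with a warning (their count is kept on
#' the returned object).
#'
#' @param scene a `"synthetic_scene"` (see [generate_timeseries()]) or a
#'   plain numeric matrix of time series, voxels in rows.
#' @param eligible optional integer indices (e.g. from [make_gm_mask()])
#'   restricting the node set; default all voxels.
#' @return an object of class `"fc_graph"`: list with `r` (correlation
#'   matrix, unit diagonal), `coords` (mm positions or `NULL`), `atlas`,
#'   `eligible_index` (graph node -> original voxel index), `excluded`
#'   (logical matrix of distance-excluded pairs, all `FALSE` until
#'   [apply_distance_exclusion()] is applied), `n_zero_variance`.
#' @export
correlation_matrix <- function(scene, eligible = NULL) {
  if (inherits(scene, "synthetic_scene")) {
    series <- scene$series
    coords <- scene$coords
    atlas <- scene$atlas
  } else {
    series <- as.matrix(scene)
    coords <- NULL
    atlas <- NULL
  }
  stopifnot(ncol(series) >= 3)
  idx <- eligible %||% seq_len(nrow(series))
  series <- series[idx, , drop = FALSE]
  v <- apply(series, 1L, stats::var)
  zv <- v <= 0 | !is.finite(v)
  if (any(zv)) {
    warning(sum(zv), " zero-variance voxel(s) removed before correlation")
    series <- series[!zv, , drop = FALSE]
    idx <- idx[!zv]
  }
  if (nrow(series) < 2L) stop("fewer than 2 usable voxels")
  r <- stats::cor(t(series))
  n <- nrow(r)
  structure(list(
    r = r,
    coords = if (!is.null(coords)) coords[idx, , drop = FALSE] else NULL,
    atlas = if (!is.null(atlas)) atlas[idx] else NULL,
    eligible_index = idx,
    excluded = matrix(FALSE, n, n),
    n_zero_variance = sum(zv)), class = "fc_graph")
}

#' Remove short-range connections
#'
#' Marks every pair of voxels whose centers lie strictly closer than `d_min`
#' mm (Euclidean) as excluded: such pairs carry no edge at any threshold and
#' contribute nothing to FCS. This guards against shared-signal artifacts
#' between nearby voxels; the default 20 mm matches the distance rule used
#' for voxel-level networks.
#'
#' @param graph an `"fc_graph"`.
#' @param coords optional `n x 3` mm coordinates; defaults to the graph's own.
#' @param d_min exclusion radius in mm (default 20, pairs at exactly `d_min`
#'   are kept).
#' @return the graph with its `excluded` matrix updated.
#' @export
apply_distance_exclusion <- function(graph, coords = NULL, d_min = 20) {
  stopifnot(inherits(graph, "fc_graph"), d_min > 0)
  coords <- coords %||% graph$coords
  if (is.null(coords)) stop("no coordinates available for distance exclusion")
  coords <- as.matrix(coords)
  n <- nrow(graph$r)
  if (nrow(coords) != n)
    stop("coords (", nrow(coords), " rows) do not match graph size (", n, ")")
  d <- as.matrix(stats::dist(coords))
  excl <- d < d_min
  diag(excl) <- FALSE
  dimnames(excl) <- NULL
  graph$excluded <- graph$excluded | excl
  graph$coords <- coords
  graph
}

#' Nodal degree at a correlation threshold
#'
#' Binarizes the graph with the rule \eqn{a_{ij} = 1} iff \eqn{r_{ij} \ge T}
#' (distance-excluded pairs never form edges) and returns each node's degree,
#' the count of suprathreshold connections to all other nodes. Only positive
#' thresholds are admitted: negative correlations never contribute.
#'
#' @param graph an `"fc_graph"`.
#' @param threshold correlation threshold `T > 0` (typical values 0.4-0.6).
#' @return integer vector of degrees, one per node.
#' @export
compute_degrees <- function(graph, threshold) {
  stopifnot(inherits(graph, "fc_graph"))
  if (threshold <= 0)
    stop("threshold must be positive: negative correlations are ignored")
  adj <- (graph$r >= threshold) & !graph$excluded
  diag(adj) <- FALSE
  as.integer(rowSums(adj))
}

#' Restrict whole-brain degrees to one subnetwork
#'
#' Subnetwork degree sequences are the *global* degrees (connections counted
#' to the whole brain) of the nodes belonging to one atlas label — not
#' within-subnetwork degrees. Values are unchanged; only the node set is
#' restricted.
#'
#' @param degrees whole-brain degree vector (from [compute_degrees()]).
#' @param atlas per-node subnetwork labels, aligned with `degrees`.
#' @param k the label to keep.
#' @return the degrees of nodes with `atlas == k`.
#' @export
subnetwork_degrees <- function(degrees, atlas, k) {
  stopifnot(length(degrees) == length(atlas))
  out <- degrees[atlas == k]
  if (length(out) == 0L) stop("no nodes carry atlas label ", k)
  out
}

#' Functional connectivity strength (weighted degree centrality)
#'
#' For each voxel `i`, \eqn{FCS(i) = \frac{1}{N} \sum_{j \ne i} z_{ij}} where
#' \eqn{z_{ij} = \mathrm{atanh}(r_{ij})} is the Fisher z-transform and the sum
#' runs over voxels with \eqn{r_{ij} > r_0} (strict) that are not
#' distance-excluded. The denominator `N` is the full eligible voxel count,
#' not the number of summed terms. The floor `r0` (default 0.2) suppresses
#' weak, noise-driven correlations. Correlations are capped just below 1
#' before the z-transform so degenerate duplicate series cannot produce
#' infinities.
#'
#' @param graph an `"fc_graph"`.
#' @param r0 correlation floor, `0 < r0 < 1`.
#' @return numeric vector of non-negative FCS values, one per node.
#' @export
compute_fcs <- function(graph, r0 = 0.2) {
  stopifnot(inherits(graph, "fc_graph"))
  if (r0 <= 0 || r0 >= 1) stop("r0 must lie strictly between 0 and 1")
  keep <- (graph$r > r0) & !graph$excluded
  diag(keep) <- FALSE
  z <- atanh(pmin(graph$r, 1 - 1e-12))
  z[!keep] <- 0
  rowSums(z) / nrow(graph$r)
}
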