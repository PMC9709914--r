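#' Cluster diameter
#'
#' Largest pairwise RMSD among the members of a cluster (generalized
#' diameter); zero for a singleton.
#'
#' @param matrix an [rmsd_matrix()].
#' @param cluster a cluster from [cluster_rmsd()], or a vector of member
#'   indices.
#' @return Nonnegative diameter (nm).
#' @export
cluster_diameter <- function(matrix, cluster) {
  members <- cluster_members(cluster)
  if (length(members) < 1L) stop("cluster is empty")
  if (length(members) == 1L) return(0)
  max(matrix[members, members])
}

cluster_members <- function(cluster) {
  if (inherits(cluster, "rmsd_cluster")) cluster$members
  else as.integer(cluster)
}

cluster_seed <- function(cluster) {
  if (inherits(cluster, "rmsd_cluster")) cluster$seed
  else as.integer(cluster)[1L]
}

#' RMSD profile of one seed configuration
#'
#' The distribution of RMSDs between a chosen frame (typically the seed of
#' a populated cluster) and every other frame, read straight off the RMSD
#' matrix row, together with a probability-density histogram. The shape of
#' this distribution — a first layer of close neighbors, a trough, then the
#' rest of the ensemble — is the basis for choosing a radial threshold with
#' [suggest_radial_threshold()].
#'
#' @param matrix an [rmsd_matrix()] with at least 2 frames.
#' @param seed frame index (1-based).
#' @param bin_width histogram bin width in nm (default 0.005).
#' @return An object of class `seed_profile`: list with `seed`, `distances`
#'   (length N - 1), `breaks`, `density` and `bin_width`. Densities
#'   integrate to 1 over the binned range.
#' @export
seed_profile <- function(matrix, seed, bin_width = 0.005) {
  if (nrow(matrix) < 2L) stop("need at least 2 frames for a profile")
  seed <- as.integer(seed)
  if (seed < 1L || seed > nrow(matrix)) stop("seed index out of range")
  d <- matrix[seed, -seed]
  breaks <- histogram_breaks(d, bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(list(seed = seed, distances = as.numeric(d), breaks = h$breaks,
                 density = h$density, bin_width = bin_width),
            class = "seed_profile")
}

histogram_breaks <- function(values, bin_width) {
  top <- max(values) + bin_width
  seq(0, top + bin_width, by = bin_width)
}

#' @export
print.seed_profile <- function(x, ...) {
  cat(sprintf("seed_profile: seed %d, %d distances in [%.4g, %.4g] nm\n",
              x$seed, length(x$distances), min(x$distances),
              max(x$distances)))
  invisible(x)
}

#' Suggest a radial clustering threshold from seed profiles
#'
#' For each profile, the probability density of seed-to-frame RMSDs is
#' smoothed with a short moving average and scanned for the end of the
#' first layer of neighbors: the first bin after the first mode where the
#' density either drops below `drop_frac` of that mode's peak or sits in a
#' strict local minimum (the "trough"). If the density never qualifies, the
#' end of the distribution's support is used. The consensus threshold is
#' the maximum of the per-profile trough locations — the largest radius at
#' which no profile's density has recovered yet — and is radial in nature,
#' i.e. a value for the RTC threshold.
#'
#' @param profiles a single [seed_profile()] or a list of them.
#' @param smooth_window moving-average window in bins (default 3).
#' @param drop_frac fraction of the first mode's peak density below which
#'   the trough is declared (default 0.05).
#' @return An object of class `threshold_suggestion`: list with `threshold`
#'   (the consensus, nm), `table` (per-profile seed, trough location, peak
#'   location/density) and the smoothing parameters. Profiles with fewer
#'   than two distinct distances are skipped with a warning.
#' @export
suggest_radial_threshold <- function(profiles, smooth_window = 3L,
                                     drop_frac = 0.05) {
  if (inherits(profiles, "seed_profile")) profiles <- list(profiles)
  if (length(profiles) < 1L) stop("need at least one profile")
  rows <- list()
  for (p in profiles) {
    stopifnot(inherits(p, "seed_profile"))
    if (length(unique(p$distances)) < 2L) {
      warning("profile for seed ", p$seed,
              " has fewer than 2 distinct distances; skipped")
      next
    }
    deep <- find_density_trough(p, smooth_window, drop_frac)
    rows[[length(rows) + 1L]] <-
      data.frame(seed = p$seed, trough = deep$trough,
                 peak = deep$peak, peak_density = deep$peak_density)
  }
  if (length(rows) == 0L) stop("no usable profiles")
  table <- do.call(rbind, rows)
  structure(list(threshold = max(table$trough), table = table,
                 smooth_window = smooth_window, drop_frac = drop_frac),
            class = "threshold_suggestion")
}

# Locate the first density trough after the first mode of a seed profile.
find_density_trough <- function(profile, smooth_window, drop_frac) {
  dens <- moving_average(profile$density, smooth_window)
  mids <- profile$breaks[-1] - profile$bin_width / 2
  nb <- length(dens)
  pad <- function(i) if (i >= 1L && i <= nb) dens[i] else -Inf
  # first mode: first local maximum carrying a non-negligible density
  floor_dens <- drop_frac * max(dens)
  mode_idx <- NA_integer_
  for (i in seq_len(nb)) {
    if (dens[i] >= pad(i - 1L) && dens[i] >= pad(i + 1L) &&
        dens[i] > floor_dens) {
      mode_idx <- i
      break
    }
  }
  if (is.na(mode_idx)) mode_idx <- which.max(dens)
  trough <- NA_real_
  for (j in seq.int(mode_idx + 1L, length.out = max(0L, nb - mode_idx))) {
    below <- dens[j] < drop_frac * dens[mode_idx]
    local_min <- dens[j] < pad(j - 1L) && dens[j] < pad(j + 1L)
    if (below || local_min) {
      trough <- mids[j]
      break
    }
  }
  if (is.na(trough)) {
    support <- which(profile$density > 0)
    trough <- profile$breaks[max(support) + 1L] # right edge of last busy bin
  }
  list(trough = trough, peak = mids[mode_idx],
       peak_density = dens[mode_idx])
}

moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' @export
print.threshold_suggestion <- function(x, ...) {
  cat(sprintf("suggested radial threshold: %.4g nm (consensus of %d profiles)\n",
              x$threshold, nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Coordinates of a cluster's members expressed in the seed's frame:
# every member is least-squares fitted onto the seed configuration
# (fit = FALSE uses the stored coordinates as-is, for prealigned data).
member_coords_in_seed_frame <- function(ensemble, cluster, fit = TRUE) {
  members <- cluster_members(cluster)
  seed <- cluster_seed(cluster)
  if (!(seed %in% members)) stop("cluster seed must be among the members")
  out <- ensemble$xyz[members, , drop = FALSE]
  if (fit) {
    ref <- frame_coords(ensemble, seed)
    for (r in seq_along(members)) {
      i <- members[r]
      if (i == seed) next
      out[r, ] <- as_coord_vec(superpose(frame_coords(ensemble, i), ref)$fitted)
    }
  }
  rownames(out) <- members
  out
}

#' Radius of gyration of a cluster
#'
#' RMS deviation of the cluster members from their center of geometry,
#' measured in RMSD units:
#' `rog = sqrt( (1/|C|) * sum_i rmsd(x_i, centroid)^2 )`.
#' Members are first least-squares fitted onto the seed configuration (the
#' one frame every member already relates to); the centroid is their
#' coordinate-wise mean. The divisor is the population size `|C|`.
#'
#' @param ensemble the [conf_ensemble()] the clustering was computed from.
#' @param cluster a cluster from [cluster_rmsd()] (or a member index vector
#'   whose first element is taken as the seed).
#' @param fit fit members to the seed first (default TRUE); use FALSE for
#'   prealigned or abstract point-cloud data.
#' @return Nonnegative radius of gyration (nm); 0 for a singleton.
#' @export
radius_of_gyration <- function(ensemble, cluster, fit = TRUE) {
  xyz <- member_coords_in_seed_frame(ensemble, cluster, fit)
  if (nrow(xyz) == 1L) return(0)
  centroid <- colMeans(xyz)
  sqrt(mean(apply(xyz, 1L, function(v) rmsd_raw(v, centroid)^2)))
}

#' RMSD between a cluster's seed and its members' center of geometry
#'
#' Members are fitted onto the seed (unless `fit = FALSE`), averaged
#' coordinate-wise, and the RMSD between the seed configuration and that
#' centroid is returned. Large values flag seeds far from the geometric
#' center of their cluster.
#'
#' @inheritParams radius_of_gyration
#' @return Nonnegative RMSD (nm); 0 for a singleton.
#' @export
seed_centroid_rmsd <- function(ensemble, cluster, fit = TRUE) {
  xyz <- member_coords_in_seed_frame(ensemble, cluster, fit)
  if (nrow(xyz) == 1L) return(0)
  centroid <- colMeans(xyz)
  seed <- cluster_seed(cluster)
  rmsd_raw(ensemble$xyz[seed, ], centroid)
}

#' Seed-distance sums and angles for all member pairs
#'
#' For every unordered pair (j, k) of non-seed members of a cluster, after
#' fitting all members to the seed i: the sum `rmsd(i,j) + rmsd(i,k)` and
#' the angle (degrees, in the full n-dimensional coordinate space) between
#' the difference vectors `x_j - x_i` and `x_k - x_i`. Pairs whose sum
#' approaches twice the radial threshold but whose angle stays well below
#' 180 degrees explain why observed cluster diameters fall short of the
#' theoretical `2 * threshold` bound.
#'
#' @inheritParams radius_of_gyration
#' @return Data frame with columns `j`, `k` (1-based frame indices),
#'   `distance_sum` (nm) and `angle_deg` in `[0, 180]`. Pairs involving a
#'   zero-length difference vector are skipped with a warning.
#' @export
pair_sum_angle <- function(ensemble, cluster, fit = TRUE) {
  members <- cluster_members(cluster)
  seed <- cluster_seed(cluster)
  if (length(members) < 3L)
    stop("need at least the seed and two other members")
  xyz <- member_coords_in_seed_frame(ensemble, cluster, fit)
  n_a <- ensemble$n_atoms
  seed_row <- which(members == seed)
  seed_vec <- xyz[seed_row, ]
  others <- setdiff(seq_along(members), seed_row)
  diffs <- sweep(xyz[others, , drop = FALSE], 2L, seed_vec)
  norms <- sqrt(rowSums(diffs^2))
  zero <- norms == 0
  if (any(zero)) {
    warning(sum(zero), " member(s) coincide with the seed; pairs skipped")
    others <- others[!zero]
    diffs <- diffs[!zero, , drop = FALSE]
    norms <- norms[!zero]
  }
  m <- length(others)
  if (m < 2L) return(data.frame(j = integer(0), k = integer(0),
                                distance_sum = numeric(0),
                                angle_deg = numeric(0)))
  pairs <- utils::combn(m, 2L)
  j <- pairs[1L, ]
  k <- pairs[2L, ]
  cosang <- rowSums(diffs[j, , drop = FALSE] * diffs[k, , drop = FALSE]) /
    (norms[j] * norms[k])
  cosang <- pmin(1, pmax(-1, cosang))
  data.frame(j = members[others][j], k = members[others][k],
             distance_sum = (norms[j] + norms[k]) / sqrt(n_a),
             angle_deg = acos(cosang) * 180 / pi)
}

#' Within-cluster RMSD distribution
#'
#' Probability-density histogram of all pairwise RMSDs among a cluster's
#' members. For a diametral (QTC) cluster the support lies strictly below
#' the threshold; split (bimodal) distributions flag clusters that merged
#' two populations.
#'
#' @param matrix an [rmsd_matrix()].
#' @param cluster a cluster or member index vector with at least 2 members.
#' @param bin_width histogram bin width in nm (default 0.005).
#' @return List with `values` (the pairwise RMSDs), `breaks` and `density`
#'   (integrating to 1).
#' @export
intra_cluster_distribution <- function(matrix, cluster, bin_width = 0.005) {
  members <- cluster_members(cluster)
  if (length(members) < 2L) stop("need at least 2 members")
  sub <- matrix[members, members]
  values <- sub[upper.tri(sub)]
  h <- graphics::hist(values, breaks = histogram_breaks(values, bin_width),
                      plot = FALSE)
  list(values = as.numeric(values), breaks = h$breaks, density = h$density)
}

#' Cluster-coverage statistics
#'
#' For each size cutoff: how many clusters have at least that many members,
#' and what percentage of all frames they contain.
#'
#' @param result an `rmsd_clustering` from [cluster_rmsd()].
#' @param size_cutoffs positive integer cutoffs (default `c(10, 100)`).
#' @return Data frame with columns `cutoff`, `n_clusters`, `coverage_pct`;
#'   the total number of clusters is attached as attribute
#'   `total_clusters`.
#' @examples
#' pts <- c(0, 1, 2, 10, 11)
#' m <- rmsd_matrix(abs(outer(pts, pts, "-")), mode = "prealigned")
#' coverage_report(cluster_rmsd(m, 1.5, "radial"), size_cutoffs = c(2, 3))
#' @export
coverage_report <- function(result, size_cutoffs = c(10L, 100L)) {
  stopifnot(inherits(result, "rmsd_clustering"))
  if (any(size_cutoffs < 1L)) stop("size cutoffs must be positive")
  sizes <- cluster_sizes(result)
  tab <- data.frame(
    cutoff = as.integer(size_cutoffs),
    n_clusters = vapply(size_cutoffs, function(c) sum(sizes >= c), integer(1)),
    coverage_pct = vapply(size_cutoffs, function(c)
      100 * sum(sizes[sizes >= c]) / result$n, numeric(1)))
  attr(tab, "total_clusters") <- length(sizes)
  tab
}
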