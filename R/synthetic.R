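# Run expr with a locally seeded, named RNG (Mersenne-Twister / Inversion /
# Rejection), restoring the caller's RNG state afterwards so generators are
# reproducible without side effects.
with_rng_seed <- function(rng_seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(rng_seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Generate an ensemble with planted, well-separated clusters
#'
#' Builds a synthetic configuration ensemble with known ground-truth
#' cluster labels: `k_clusters` centers are placed by rejection sampling in
#' a hypercube so that every pair of centers is at least `min_separation`
#' apart *in RMSD units*, and members are drawn isotropically Gaussian
#' (standard deviation `intra_spread` per coordinate) around their center.
#' Intended for recovery tests and threshold-selection fixtures: intra- and
#' inter-cluster RMSDs then live on scales of roughly
#' `intra_spread * sqrt(6)` and `min_separation`. These are abstract point
#' clouds (no molecular structure); use the `"prealigned"` metric mode on
#' them.
#'
#' @param k_clusters number of planted clusters.
#' @param members_per_cluster integer (recycled) or vector of cluster sizes.
#' @param n_atoms atoms per configuration (dimension is `3 * n_atoms`).
#' @param intra_spread Gaussian standard deviation per coordinate (nm).
#' @param min_separation minimum center-to-center RMSD (nm). For
#'   "well-separated" fixtures keep it a few times
#'   `2 * intra_spread * sqrt(3)`.
#' @param seed_at_mean if TRUE (default) the first member of each cluster
#'   is the exact center.
#' @param rng_seed integer seed; same seed, same ensemble, bit for bit.
#' @param max_tries rejection-sampling attempts per center before giving
#'   up.
#' @return List with `ensemble` (a [conf_ensemble()]), `labels` (integer
#'   ground truth per frame), `centers` (k x 3n matrix) and `rng_seed`.
#' @examples
#' fix <- generate_planted_ensemble(3, 50, rng_seed = 1)
#' table(fix$labels)
#' @export
generate_planted_ensemble <- function(k_clusters = 3L,
                                      members_per_cluster = 100L,
                                      n_atoms = 5L,
                                      intra_spread = 0.02,
                                      min_separation = 0.5,
                                      seed_at_mean = TRUE,
                                      rng_seed = 1L,
                                      max_tries = 2000L) {
  k_clusters <- as.integer(k_clusters)
  if (k_clusters < 1L) stop("k_clusters must be >= 1")
  sizes <- rep_len(as.integer(members_per_cluster), k_clusters)
  if (any(sizes < 1L)) stop("cluster sizes must be positive")
  if (intra_spread < 0) stop("intra_spread must be >= 0")
  if (min_separation <= 0) stop("min_separation must be positive")
  n <- 3L * as.integer(n_atoms)
  sep_euclid <- min_separation * sqrt(n_atoms)
  side <- 4 * sep_euclid # roomy enough for rejection sampling in >= 3 dims

  with_rng_seed(rng_seed, {
    centers <- matrix(NA_real_, k_clusters, n)
    for (c in seq_len(k_clusters)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- runif(n, 0, side)
        ok <- c == 1L || all(sqrt(colSums((t(centers[seq_len(c - 1L), ,
                             drop = FALSE]) - cand)^2)) >= sep_euclid)
        if (ok) {
          centers[c, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place cluster centers at the requested separation")
    }
    coords <- matrix(NA_real_, sum(sizes), n)
    labels <- integer(sum(sizes))
    row <- 0L
    for (c in seq_len(k_clusters)) {
      for (mem in seq_len(sizes[c])) {
        row <- row + 1L
        coords[row, ] <- if (seed_at_mean && mem == 1L) centers[c, ]
          else centers[c, ] + rnorm(n, 0, intra_spread)
        labels[row] <- c
      }
    }
    list(ensemble = conf_ensemble(coords, n_atoms = n_atoms),
         labels = labels, centers = centers, rng_seed = as.integer(rng_seed))
  })
}

#' Generate a 2-D point set (structureless or multimodal)
#'
#' Produces N points in the plane for desk-scale clustering experiments.
#' Profile `"disk"` (default) draws points uniformly from a disk — dense
#' data with no underlying cluster structure, on which radial clustering at
#' half the diametral threshold and diametral clustering behave alike.
#' `"gaussian"` is a single broad isotropic normal; `"blobs"` superimposes
#' Gaussian modes at supplied centers.
#'
#' @param n_points number of points (>= 1).
#' @param profile `"disk"`, `"gaussian"` or `"blobs"`.
#' @param rng_seed integer seed; output is bit-identical across runs.
#' @param radius disk radius / Gaussian standard deviation scale (default
#'   10).
#' @param centers 2-column matrix of mode centers (profile `"blobs"`).
#' @param blob_sd per-coordinate standard deviation for `"blobs"`.
#' @return N x 2 numeric matrix of coordinates.
#' @seealso [points_ensemble()] to wrap the points for [cluster_rmsd()].
#' @export
generate_2d_mixture <- function(n_points, profile = c("disk", "gaussian",
                                                      "blobs"),
                                rng_seed = 1L, radius = 10,
                                centers = NULL, blob_sd = 1) {
  profile <- match.arg(profile)
  n_points <- as.integer(n_points)
  if (n_points < 1L) stop("n_points must be >= 1")
  with_rng_seed(rng_seed, {
    pts <- switch(profile,
      disk = {
        r <- radius * sqrt(runif(n_points))
        a <- runif(n_points, 0, 2 * pi)
        cbind(r * cos(a), r * sin(a))
      },
      gaussian = cbind(rnorm(n_points, 0, radius),
                       rnorm(n_points, 0, radius)),
      blobs = {
        if (is.null(centers)) stop("profile 'blobs' needs centers")
        centers <- as.matrix(centers)
        pick <- sample.int(nrow(centers), n_points, replace = TRUE)
        centers[pick, , drop = FALSE] +
          cbind(rnorm(n_points, 0, blob_sd), rnorm(n_points, 0, blob_sd))
      })
    unname(pts)
  })
}

#' Wrap a 2-D point set as a configuration ensemble
#'
#' Embeds each point as a single-atom configuration (z = 0) so the
#' prealigned RMSD equals the planar Euclidean distance, making 2-D point
#' sets directly usable with [pairwise_rmsd_matrix()] and [cluster_rmsd()].
#'
#' @param points N x 2 numeric matrix.
#' @return A [conf_ensemble()] with one atom per frame.
#' @export
points_ensemble <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must have 2 columns")
  conf_ensemble(cbind(points, 0), n_atoms = 1L)
}

#' Project an ensemble to the plane of one atom
#'
#' Fits every frame to a reference frame, then extracts the (x, y)
#' coordinates of one chosen atom per frame — a simple 2-D shadow of the
#' ensemble, invariant to any global rigid motion of the input.
#'
#' @param ensemble a [conf_ensemble()].
#' @param atom 1-based atom index.
#' @param ref_frame 1-based reference frame index.
#' @return N x 2 matrix of projected coordinates.
#' @export
project_to_2d <- function(ensemble, atom, ref_frame) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  atom <- as.integer(atom)
  if (atom < 1L || atom > ensemble$n_atoms) stop("atom index out of range")
  fitted <- fit_all_to_reference(ensemble, ref_frame)
  cols <- c(3L * atom - 2L, 3L * atom - 1L)
  fitted$xyz[, cols, drop = FALSE]
}

#' Regular subsampling
#'
#' Keeps the elements at positions `start`, `start + stride`,
#' `start + 2 * stride`, ... (1-based), preserving order. Works on vectors,
#' matrices / data frames (rows) and [conf_ensemble()] objects (frames).
#'
#' @param items the collection to subsample.
#' @param stride positive step between kept positions.
#' @param start 1-based first position; if beyond the length, the result is
#'   empty.
#' @return The subsampled collection, same type as the input.
#' @examples
#' length(subsample(seq_len(6001), 4)) # 1501
#' @export
subsample <- function(items, stride, start = 1L) {
  stride <- as.integer(stride)
  start <- as.integer(start)
  if (stride < 1L) stop("stride must be >= 1")
  if (start < 1L) stop("start must be >= 1")
  n <- if (inherits(items, "conf_ensemble")) n_frames(items) else NROW(items)
  if (start > n) idx <- integer(0) else idx <- seq.int(start, n, by = stride)
  if (inherits(items, "conf_ensemble")) {
    if (length(idx) == 0L) stop("subsample of an ensemble cannot be empty")
    subset_frames(items, idx)
  } else if (is.matrix(items) || is.data.frame(items)) {
    items[idx, , drop = FALSE]
  } else {
    items[idx]
  }
}
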