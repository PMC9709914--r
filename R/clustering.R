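#' Clustering bookkeeping state
#'
#' Tracks which frame indices are still available for clustering, which have
#' been assigned in earlier iterations, and the current iteration number.
#'
#' @param n_frames total number of frames.
#' @return A list with `available` (ascending 1-based indices), `clustered`
#'   (empty at the start) and `iteration = 1`.
#' @export
clustering_state <- function(n_frames) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  list(available = seq_len(n_frames), clustered = integer(0), iteration = 1L)
}

#' Radial neighbor set of a seed
#'
#' All available frames strictly within the threshold of the seed (the seed
#' itself always qualifies, its self-RMSD being zero). Frames at exactly the
#' threshold are excluded.
#'
#' @param matrix an [rmsd_matrix()] (any symmetric RMSD matrix works).
#' @param k seed index (1-based); must be in `available`.
#' @param available ascending vector of available frame indices.
#' @param threshold positive radial threshold (nm).
#' @return The indices `i` in `available` with `matrix[k, i] < threshold`.
#' @export
neighbor_set <- function(matrix, k, available, threshold) {
  if (!(k %in% available)) stop("seed ", k, " is not available")
  if (threshold <= 0) stop("threshold must be positive")
  available[matrix[k, available] < threshold]
}

new_cluster <- function(rank, seed, members, threshold, kind) {
  structure(list(rank = as.integer(rank), seed = as.integer(seed),
                 members = sort(as.integer(members)),
                 threshold = threshold, kind = kind),
            class = "rmsd_cluster")
}

#' @export
print.rmsd_cluster <- function(x, ...) {
  cat(sprintf("cluster %d: seed %d, %d members (%s threshold %g)\n",
              x$rank, x$seed, length(x$members), x$kind, x$threshold))
  invisible(x)
}

iteration_record <- function(available, sizes, f) {
  winners <- available[sizes == max(sizes)]
  list(sizes = stats::setNames(sizes, available), winners = winners,
       chosen_seed = as.integer(f(winners)))
}

#' One iteration of radial-threshold clustering
#'
#' Every available frame proposes its radial neighbor set; the proposals are
#' compared by size and the largest one (ties resolved by `f`, by default
#' the lowest seed index) becomes this iteration's cluster. Its members are
#' removed from the available pool.
#'
#' @param matrix an [rmsd_matrix()].
#' @param state a [clustering_state()].
#' @param threshold positive radial threshold (nm).
#' @param f tie-break rule mapping the set of winning seeds to one seed;
#'   default [min].
#' @return List with `cluster` (the emitted cluster), `record` (per-seed
#'   tentative sizes, the winning seeds, and the chosen seed) and `state`
#'   (updated).
#' @export
rtc_iteration <- function(matrix, state, threshold, f = min) {
  avail <- state$available
  if (length(avail) == 0L) stop("no frames available")
  sizes <- rtc_counts_cpp(matrix, avail - 1L, threshold)
  record <- iteration_record(avail, sizes, f)
  members <- neighbor_set(matrix, record$chosen_seed, avail, threshold)
  cl <- new_cluster(state$iteration, record$chosen_seed, members, threshold,
                    "radial")
  list(cluster = cl, record = record,
       state = list(available = setdiff(avail, members),
                    clustered = sort(c(state$clustered, members)),
                    iteration = state$iteration + 1L))
}

#' Greedy diametral growth of a tentative cluster
#'
#' Implements the quality-threshold growth procedure: starting from the seed
#' alone, repeatedly add the available frame whose inclusion increases the
#' cluster diameter (largest pairwise RMSD) the least, provided the
#' resulting diameter stays strictly below the threshold; stop when no
#' candidate qualifies. Exact ties on the resulting diameter are broken by
#' the lowest frame index. Only frames strictly within the threshold of the
#' seed can ever qualify, so the candidate pool is restricted to the seed's
#' radial neighborhood (this does not change the result).
#'
#' @inheritParams neighbor_set
#' @param threshold positive diametral threshold (nm).
#' @return List with `seed`, `members` (in inclusion order, seed first) and
#'   `diameter` (largest pairwise RMSD among the members).
#' @export
qtc_grow <- function(matrix, k, available, threshold) {
  if (!(k %in% available)) stop("seed ", k, " is not available")
  if (threshold <= 0) stop("threshold must be positive")
  res <- qtc_grow_cpp(matrix, k - 1L, as.integer(available) - 1L, threshold)
  list(seed = as.integer(k), members = res$members + 1L,
       diameter = res$diameter)
}

#' One iteration of quality (diametral) threshold clustering
#'
#' Grows a tentative cluster from every available seed with [qtc_grow()],
#' then promotes the largest one (ties resolved by `f`, default lowest seed
#' index) to be this iteration's cluster.
#'
#' @inheritParams rtc_iteration
#' @param threshold positive diametral threshold (nm).
#' @return Same structure as [rtc_iteration()].
#' @export
qtc_iteration <- function(matrix, state, threshold, f = min) {
  avail <- state$available
  if (length(avail) == 0L) stop("no frames available")
  res <- qtc_iter_cpp(matrix, avail - 1L, threshold)
  record <- iteration_record(avail, res$sizes, f)
  grown <- qtc_grow(matrix, record$chosen_seed, avail, threshold)
  cl <- new_cluster(state$iteration, record$chosen_seed, grown$members,
                    threshold, "diametral")
  list(cluster = cl, record = record,
       state = list(available = setdiff(avail, grown$members),
                    clustered = sort(c(state$clustered, grown$members)),
                    iteration = state$iteration + 1L))
}

#' Cluster an RMSD matrix with the RTC or QTC algorithm
#'
#' Iterates [rtc_iteration()] (radial threshold) or [qtc_iteration()]
#' (diametral threshold) until no frames remain or the newly produced
#' cluster has fewer than `min_size` members; that undersized cluster is not
#' emitted and all remaining frames are reported as unassigned. With
#' `min_size = 1` the clusters always partition all frames.
#'
#' @param matrix an [rmsd_matrix()] (or any symmetric nonnegative matrix
#'   with zero diagonal).
#' @param threshold positive threshold value (nm); radial for
#'   `kind = "radial"` (RTC), diametral for `kind = "diametral"` (QTC).
#' @param kind `"radial"` or `"diametral"`.
#' @param min_size minimum cluster size at which iteration continues
#'   (default 1).
#' @param f tie-break rule over winning seed indices; default [min]. Any
#'   other choice switches to the (slower) per-iteration R driver.
#' @return An object of class `rmsd_clustering`: list with `clusters` (list
#'   of clusters, each with `rank`, `seed`, sorted `members`, `threshold`,
#'   `kind`), `algorithm` (`"RTC"` or `"QTC"`), `threshold`, `min_size`,
#'   `unassigned` (sorted indices) and `n` (total frames).
#' @examples
#' pts <- c(0, 1, 2, 10, 11) # five 1-D configurations
#' m <- rmsd_matrix(abs(outer(pts, pts, "-")), mode = "prealigned")
#' cluster_rmsd(m, threshold = 1.5, kind = "radial")
#' @export
cluster_rmsd <- function(matrix, threshold,
                         kind = c("radial", "diametral"),
                         min_size = 1L, f = min) {
  kind <- match.arg(kind)
  min_size <- as.integer(min_size)
  if (is.na(min_size) || min_size < 1L) stop("min_size must be >= 1")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  algorithm <- if (kind == "radial") "RTC" else "QTC"
  n <- nrow(matrix)

  if (identical(f, min)) {
    raw <- cluster_full_cpp(matrix, threshold, kind == "radial", min_size)
    clusters <- vector("list", length(raw$seeds))
    for (m in seq_along(raw$seeds)) {
      clusters[[m]] <- new_cluster(m, raw$seeds[m] + 1L,
                                   raw$members[[m]] + 1L, threshold, kind)
    }
    unassigned <- raw$unassigned + 1L
  } else {
    state <- clustering_state(n)
    step_fun <- if (kind == "radial") rtc_iteration else qtc_iteration
    clusters <- list()
    while (length(state$available) > 0L) {
      step <- step_fun(matrix, state, threshold, f)
      if (length(step$cluster$members) < min_size) break
      clusters[[length(clusters) + 1L]] <- step$cluster
      state <- step$state
    }
    unassigned <- state$available
  }

  structure(list(clusters = clusters, algorithm = algorithm,
                 threshold = threshold, min_size = min_size,
                 unassigned = as.integer(sort(unassigned)), n = n),
            class = "rmsd_clustering")
}

#' Cluster sizes in rank order
#' @param result an `rmsd_clustering` from [cluster_rmsd()].
#' @return Integer vector of member counts, one per cluster.
#' @export
cluster_sizes <- function(result) {
  stopifnot(inherits(result, "rmsd_clustering"))
  vapply(result$clusters, function(cl) length(cl$members), integer(1))
}

#' Frame-to-cluster membership vector
#' @param result an `rmsd_clustering` from [cluster_rmsd()].
#' @return Integer vector of length `result$n`: the cluster rank of each
#'   frame, with 0 for unassigned frames.
#' @export
membership <- function(result) {
  stopifnot(inherits(result, "rmsd_clustering"))
  out <- integer(result$n)
  for (cl in result$clusters) out[cl$members] <- cl$rank
  out
}

#' @export
print.rmsd_clustering <- function(x, ...) {
  sizes <- cluster_sizes(x)
  cat(sprintf("%s clustering: %d frames, threshold %g (%s), min_size %d\n",
              x$algorithm, x$n, x$threshold,
              if (x$algorithm == "RTC") "radial" else "diametral", x$min_size))
  cat(sprintf("  %d clusters, %d unassigned\n", length(sizes),
              length(x$unassigned)))
  if (length(sizes))
    cat("  sizes:", paste(utils::head(sizes, 10L), collapse = " "),
        if (length(sizes) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Write the frame-assignment table
#'
#' One row per frame: `frame_id` (1-based frame number), `cluster_rank`
#' (0 for unassigned) and `is_seed`.
#'
#' @param result an `rmsd_clustering`.
#' @param file output TSV path.
#' @return The table, invisibly.
#' @export
write_assignments <- function(result, file) {
  ranks <- membership(result)
  seeds <- vapply(result$clusters, `[[`, integer(1), "seed")
  tab <- data.frame(frame_id = seq_len(result$n), cluster_rank = ranks,
                    is_seed = as.integer(seq_len(result$n) %in% seeds))
  write_tsv_with_header(tab, file, c(
    sprintf("algorithm=%s threshold=%g min_size=%d", result$algorithm,
            result$threshold, result$min_size),
    "frame_id is 1-based; cluster_rank 0 means unassigned"))
  invisible(tab)
}

#' Write the per-cluster summary table
#'
#' One row per cluster: rank, 1-based seed frame, size and diameter
#' (largest within-cluster pairwise RMSD); a final rank-0 row summarizes the
#' unassigned frames, if any.
#'
#' @param result an `rmsd_clustering`.
#' @param matrix the RMSD matrix the clustering was computed from.
#' @param file output TSV path.
#' @return The table, invisibly.
#' @export
write_cluster_summary <- function(result, matrix, file) {
  rows <- lapply(result$clusters, function(cl) {
    data.frame(rank = cl$rank, seed_frame = cl$seed,
               size = length(cl$members),
               diameter = cluster_diameter(matrix, cl))
  })
  tab <- do.call(rbind, c(rows, list(
    if (length(result$unassigned))
      data.frame(rank = 0L, seed_frame = NA_integer_,
                 size = length(result$unassigned), diameter = NA_real_))))
  if (is.null(tab))
    tab <- data.frame(rank = integer(0), seed_frame = integer(0),
                      size = integer(0), diameter = numeric(0))
  write_tsv_with_header(tab, file, c(
    sprintf("algorithm=%s threshold=%g min_size=%d", result$algorithm,
            result$threshold, result$min_size),
    "seed_frame is 1-based; rank 0 collects unassigned frames"))
  invisible(tab)
}

write_tsv_with_header <- function(tab, file, comments = character(0)) {
  con <- file(file, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
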