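# Independent re-implementations used as oracles. These deliberately avoid
# the package's code paths: plain R, no candidate-pool restriction, diameters
# recomputed from scratch at every step.

# Distance matrix of a random point cloud (a valid, metric rmsd matrix).
random_point_matrix <- function(n, d = 2, scale = 1) {
  pts <- matrix(runif(n * d, 0, scale), n, d)
  rmsd_matrix(as.matrix(dist(pts)), mode = "prealigned")
}

# Random symmetric nonnegative matrix with zero diagonal (not necessarily
# metric; the algorithms only assume symmetry).
random_symmetric_matrix <- function(n, scale = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0, scale)
  rmsd_matrix(m + t(m), mode = "prealigned")
}

# One radial iteration by exhaustive recount, winner = lowest index among
# the largest neighborhoods.
rtc_iteration_oracle <- function(D, avail, th) {
  counts <- vapply(avail, function(k) sum(D[k, avail] < th), integer(1))
  winners <- avail[counts == max(counts)]
  seed <- min(winners)
  list(seed = seed, members = avail[D[seed, avail] < th],
       sizes = counts, winners = winners)
}

# Greedy diametral growth, re-simulated step by step over the UNRESTRICTED
# available pool, with the diameter recomputed from scratch at every step.
# Ties on the resulting diameter go to the lowest frame index.
qtc_grow_oracle <- function(D, k, avail, th) {
  members <- k
  cand <- setdiff(avail, k)
  repeat {
    best <- NA_integer_
    best_nd <- Inf
    for (c in sort(cand)) {
      trial <- c(members, c)
      nd <- max(D[trial, trial])
      if (nd < th && nd < best_nd) {
        best_nd <- nd
        best <- c
      }
    }
    if (is.na(best)) break
    members <- c(members, best)
    cand <- setdiff(cand, best)
  }
  members
}

qtc_iteration_oracle <- function(D, avail, th) {
  grown <- lapply(avail, function(k) qtc_grow_oracle(D, k, avail, th))
  sizes <- lengths(grown)
  winners <- avail[sizes == max(sizes)]
  seed <- min(winners)
  list(seed = seed, members = grown[[match(seed, avail)]], sizes = sizes)
}

# Full clustering by iterating the oracles (min_size = 1).
cluster_oracle <- function(D, th, kind) {
  avail <- seq_len(nrow(D))
  out <- list()
  while (length(avail) > 0) {
    it <- if (kind == "radial") rtc_iteration_oracle(D, avail, th)
          else qtc_iteration_oracle(D, avail, th)
    out[[length(out) + 1]] <- list(seed = it$seed,
                                   members = sort(it$members))
    avail <- setdiff(avail, it$members)
  }
  out
}

# Best proper-rotation rmsd by brute force over an Euler-angle grid
# (translations removed by centering). Grid resolution limits accuracy.
grid_superpose_oracle <- function(mobile, reference, n_grid = 24) {
  M <- sweep(mobile, 2, colMeans(mobile))
  R <- sweep(reference, 2, colMeans(reference))
  n_a <- nrow(M)
  best <- Inf
  alphas <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  betas <- seq(0, pi, length.out = n_grid)
  for (a in alphas) for (b in betas) for (g in alphas) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
    Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3)
    rot <- Rz1 %*% Ry %*% Rz2
    v <- sqrt(sum((M %*% rot - R)^2) / n_a)
    if (v < best) best <- v
  }
  best
}

# Random proper rotation + translation applied to an n_a x 3 configuration.
random_rigid_transform <- function(coords) {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(coords %*% q, 2, rnorm(3, 0, 2), "+")
}

# Adjusted Rand index between two labelings (independent of mclust).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
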