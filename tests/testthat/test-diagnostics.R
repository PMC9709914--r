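two_cluster_fixture <- function(rng_seed = 7, spread = 0.02, sep = 0.6) {
  generate_planted_ensemble(k_clusters = 2, members_per_cluster = 60,
                            n_atoms = 5, intra_spread = spread,
                            min_separation = sep, rng_seed = rng_seed)
}

test_that("cluster diameter is the largest pairwise rmsd", {
  pts <- c(0, 0.4, 1.0)
  m <- rmsd_matrix(abs(outer(pts, pts, "-")), mode = "prealigned")
  expect_identical(cluster_diameter(m, 2L), 0)
  expect_equal(cluster_diameter(m, c(1L, 2L)), 0.4)
  expect_equal(cluster_diameter(m, 1:3), 1.0)
  q <- cluster_rmsd(m, 0.5, "diametral")
  for (cl in q$clusters) expect_lt(cluster_diameter(m, cl), 0.5)
})

test_that("seed profiles carry the matrix row and a proper density", {
  pts <- c(0, 0.1, 0.3)
  m <- rmsd_matrix(abs(outer(pts, pts, "-")), mode = "prealigned")
  p <- seed_profile(m, 1)
  expect_identical(sort(p$distances), c(0.1, 0.3))
  expect_length(p$distances, 2L)
  expect_equal(sum(p$density * diff(p$breaks)), 1)
  expect_error(seed_profile(rmsd_matrix(matrix(0, 1, 1)), 1), "2 frames")

  z <- rmsd_matrix(matrix(0, 4, 4), mode = "prealigned")
  expect_identical(seed_profile(z, 2)$distances, rep(0, 3))
})

test_that("two-population fixtures give bimodal profiles with an empty gap", {
  fix <- two_cluster_fixture()
  m <- pairwise_rmsd_matrix(fix$ensemble, "prealigned")
  p <- seed_profile(m, 1) # seed 1 sits at the first planted center
  own <- fix$labels == fix$labels[1]
  intra <- p$distances[own[-1]]
  inter <- p$distances[!own[-1]]
  expect_lt(max(intra), 0.2)
  expect_gt(min(inter), 0.4)
  # no mass inside the gap
  gap_bins <- p$breaks[-length(p$breaks)] >= max(intra) &
    p$breaks[-1] <= min(inter)
  expect_true(all(p$density[gap_bins] == 0))
})

test_that("threshold suggestion lands in the density gap and is idempotent", {
  fix <- two_cluster_fixture()
  m <- pairwise_rmsd_matrix(fix$ensemble, "prealigned")
  seeds <- c(1L, 61L) # the two planted centers
  profiles <- lapply(seeds, function(s) seed_profile(m, s))
  sug <- suggest_radial_threshold(profiles)
  own <- lapply(seeds, function(s) m[s, fix$labels == fix$labels[s]])
  spread_edge <- max(unlist(own))
  sep_edge <- min(m[1, fix$labels != fix$labels[1]])
  expect_gt(sug$threshold, 0.02) # above the planted per-coordinate spread
  expect_lt(sug$threshold, 0.6)  # below the planted separation
  expect_lt(sug$threshold, sep_edge)
  # clustering at the suggestion recovers the planted split
  r <- cluster_rmsd(m, sug$threshold, "radial")
  expect_equal(ari(membership(r), fix$labels), 1)

  # duplicated profiles change nothing (consensus is a max)
  dup <- suggest_radial_threshold(c(profiles, profiles))
  expect_identical(dup$threshold, sug$threshold)
  one <- suggest_radial_threshold(profiles[[1]])
  expect_identical(one$threshold, sug$table$trough[1])
})

test_that("flat profiles fall back to the end of support; degenerate skipped", {
  # near-uniform distances: density never drops below the trough fraction,
  # so the suggestion is the end of the support
  m <- matrix(0, 42, 42)
  d <- seq(0.1, 0.5, by = 0.01)
  m[1, 2:42] <- d
  m[2:42, 1] <- d
  for (i in 2:42) for (j in 2:42) m[i, j] <- abs(d[i - 1] - d[j - 1]) + 0.3
  for (i in 2:42) m[i, i] <- 0
  p <- seed_profile(rmsd_matrix(m, mode = "prealigned"), 1, bin_width = 0.1)
  sug <- suggest_radial_threshold(p)
  expect_gte(sug$threshold, max(d))

  z <- rmsd_matrix(matrix(0, 3, 3), mode = "prealigned")
  pz <- seed_profile(z, 1)
  expect_warning(expect_error(suggest_radial_threshold(pz), "no usable"),
                 "skipped")
})

test_that("radius of gyration matches closed forms and Monte Carlo", {
  # singleton
  ens1 <- conf_ensemble(matrix(rnorm(6), nrow = 2), n_atoms = 1)
  expect_identical(radius_of_gyration(ens1, 1L), 0)
  # two single-atom 1-D frames at 0 and d: centroid halfway
  d <- 0.8
  ens2 <- conf_ensemble(rbind(c(0, 0, 0), c(d, 0, 0)), n_atoms = 1)
  expect_equal(radius_of_gyration(ens2, c(1L, 2L), fit = FALSE), d / 2)
  expect_equal(seed_centroid_rmsd(ens2, c(1L, 2L), fit = FALSE), d / 2)

  # isotropic Gaussian cluster: rog -> sigma * sqrt(3)
  sigma <- 0.05
  fix <- generate_planted_ensemble(1, 500, n_atoms = 4,
                                   intra_spread = sigma,
                                   min_separation = 1, rng_seed = 11)
  rog <- radius_of_gyration(fix$ensemble, seq_len(500), fit = FALSE)
  expect_equal(rog, sigma * sqrt(3), tolerance = 0.1)
})

test_that("seed-to-centroid rmsd is small for a seed planted at the mean", {
  sigma <- 0.05
  fix <- generate_planted_ensemble(1, 400, n_atoms = 4,
                                   intra_spread = sigma,
                                   min_separation = 1, seed_at_mean = TRUE,
                                   rng_seed = 12)
  d <- seed_centroid_rmsd(fix$ensemble, seq_len(400), fit = FALSE)
  expect_lt(d, 4 * sigma / sqrt(400) * sqrt(3) * 5) # sampling-noise scale
  # never exceeds the largest member-to-centroid rmsd
  xyz <- fix$ensemble$xyz
  centroid <- colMeans(xyz)
  maxdev <- max(apply(xyz, 1, function(v) rmsd_raw(v, centroid)))
  expect_lte(d, maxdev)
})

test_that("pair angles recover collinear and orthogonal geometry", {
  # single-atom 1-D frames: seed at 0, members at +1 and +2
  ens <- conf_ensemble(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                       n_atoms = 1)
  rec <- pair_sum_angle(ens, structure(list(seed = 1L, members = 1:3),
                                       class = "rmsd_cluster"), fit = FALSE)
  expect_equal(rec$angle_deg, 0)
  expect_equal(rec$distance_sum, 3)

  ens2 <- conf_ensemble(rbind(c(0, 0, 0), c(-1, 0, 0), c(1, 0, 0)),
                        n_atoms = 1)
  rec2 <- pair_sum_angle(ens2, structure(list(seed = 1L, members = 1:3),
                                         class = "rmsd_cluster"),
                         fit = FALSE)
  expect_equal(rec2$angle_deg, 180)
  expect_equal(rec2$distance_sum, 2)

  ens3 <- conf_ensemble(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        n_atoms = 1)
  rec3 <- pair_sum_angle(ens3, structure(list(seed = 1L, members = 1:3),
                                         class = "rmsd_cluster"),
                         fit = FALSE)
  expect_equal(rec3$angle_deg, 90)

  dup <- conf_ensemble(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                       n_atoms = 1)
  expect_warning(pair_sum_angle(dup, structure(list(seed = 1L,
                                                    members = 1:3),
                                               class = "rmsd_cluster"),
                                fit = FALSE), "coincide")
})

test_that("distance sums bound the diameter for radial clusters", {
  set.seed(301)
  pts <- matrix(runif(160), ncol = 2)
  ens <- points_ensemble(pts)
  m <- pairwise_rmsd_matrix(ens, "prealigned")
  th <- 0.2
  r <- cluster_rmsd(m, th, "radial")
  for (cl in r$clusters) {
    if (length(cl$members) < 3) next
    rec <- pair_sum_angle(ens, cl, fit = FALSE)
    expect_lt(max(rec$distance_sum), 2 * th)
    expect_lte(cluster_diameter(m, cl), max(rec$distance_sum) + 1e-12)
  }
})

test_that("intra-cluster distributions detect merged populations", {
  pts <- c(0, 0.02, 0.04, 0.5, 0.52, 0.54)
  m <- rmsd_matrix(abs(outer(pts, pts, "-")), mode = "prealigned")
  expect_error(intra_cluster_distribution(m, 3L), "2 members")

  h2 <- intra_cluster_distribution(m, c(1L, 4L), bin_width = 0.01)
  expect_identical(h2$values, 0.5)
  expect_equal(sum(h2$density * diff(h2$breaks)), 1)

  merged <- intra_cluster_distribution(m, 1:6, bin_width = 0.01)
  # bimodal: mass near 0 and near 0.5, nothing in between
  mids <- merged$breaks[-1] - 0.005
  expect_true(any(merged$density[mids < 0.1] > 0))
  expect_true(any(merged$density[mids > 0.4] > 0))
  expect_true(all(merged$density[mids > 0.1 & mids < 0.4] == 0))

  # QTC quality guarantee: support strictly below the threshold
  q <- cluster_rmsd(m, 0.1, "diametral")
  big <- q$clusters[[1]]
  hq <- intra_cluster_distribution(m, big, bin_width = 0.01)
  expect_lt(max(hq$values), 0.1)
})

test_that("coverage statistics follow the definition", {
  sizes <- c(6L, 3L, 1L)
  mk <- function(sizes, n) {
    clusters <- list()
    at <- 1L
    for (i in seq_along(sizes)) {
      clusters[[i]] <- structure(list(rank = i, seed = at,
                                      members = seq.int(at, at + sizes[i] - 1L),
                                      threshold = 1, kind = "radial"),
                                 class = "rmsd_cluster")
      at <- at + sizes[i]
    }
    structure(list(clusters = clusters, algorithm = "RTC", threshold = 1,
                   min_size = 1L, unassigned = setdiff(seq_len(n),
                                                       seq_len(at - 1L)),
                   n = n), class = "rmsd_clustering")
  }
  res <- mk(sizes, 10L)
  cov <- coverage_report(res, c(3L, 1L, 7L))
  expect_identical(cov$n_clusters, c(2L, 3L, 0L))
  expect_equal(cov$coverage_pct, c(90, 100, 0))
  expect_identical(attr(cov, "total_clusters"), 3L)
})

test_that("diametral seeds sit further from their centroid than radial ones", {
  # 25 planted clusters, random (non-central) first members; thresholds
  # between the cluster radius and the separation so radial winners must be
  # near-central seeds while diametral growth tolerates boundary seeds
  sigma <- 0.03
  fix <- generate_planted_ensemble(25, 60, n_atoms = 3,
                                   intra_spread = sigma,
                                   min_separation = 1.2,
                                   seed_at_mean = FALSE, rng_seed = 31)
  m <- pairwise_rmsd_matrix(fix$ensemble, "prealigned")
  # radial threshold between the typical cluster radius (sigma * sqrt(3))
  # and the typical diameter, so radial winners must be near-central seeds
  # while any seed can grow the full cluster diametrally
  th_r <- 1.8 * sigma * sqrt(3)
  th_d <- 2 * th_r
  r <- cluster_rmsd(m, th_r, "radial")
  q <- cluster_rmsd(m, th_d, "diametral")
  memb_r <- membership(r)
  memb_q <- membership(q)
  wins <- 0L
  total <- 0L
  for (lab in unique(fix$labels)) {
    idx <- which(fix$labels == lab)
    rk_r <- unique(memb_r[idx])
    rk_q <- unique(memb_q[idx])
    if (length(rk_r) != 1 || length(rk_q) != 1) next # cluster split: skip
    cl_r <- r$clusters[[rk_r]]
    cl_q <- q$clusters[[rk_q]]
    d_r <- seed_centroid_rmsd(fix$ensemble, cl_r, fit = FALSE)
    d_q <- seed_centroid_rmsd(fix$ensemble, cl_q, fit = FALSE)
    total <- total + 1L
    if (d_q > d_r) wins <- wins + 1L
  }
  expect_gte(total, 20L)
  expect_gt(wins / total, 0.5)
})
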