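test_that("free energies follow the Boltzmann inversion closed form", {
  # two occupied bins, counts 80000 and 20000, T = 300 K
  cv1 <- c(rep(1, 80000), rep(3, 20000))
  cv2 <- c(rep(1, 80000), rep(3, 20000))
  grid <- pmf_2d(cv1, cv2, bins = list(c(0, 2, 4), c(0, 2, 4)))
  G <- grid$G
  expect_equal(G[1, 1], 0)
  expect_equal(G[2, 2], 0.0019872 * 300 * log(4), tolerance = 1e-12)
  # empty bins are undefined, not zero
  expect_true(is.na(G[1, 2]))

  # flat landscape: all occupied bins at G = 0
  cvf <- rep(c(0.5, 1.5, 2.5), each = 100)
  gf <- pmf_2d(cvf, cvf, bins = list(c(0, 1, 2, 3), c(0, 1, 2, 3)))
  expect_equal(unname(gf$G[!is.na(gf$G)]), c(0, 0, 0))

  expect_error(pmf_2d(numeric(0), numeric(0)), "empty")
})

test_that("pmf is invariant to frame order and count scaling", {
  set.seed(6)
  cv1 <- rnorm(3000, 5); cv2 <- rnorm(3000, 7)
  b <- list(seq(0, 10, 0.5), seq(2, 12, 0.5))
  g1 <- pmf_2d(cv1, cv2, bins = b)
  perm <- sample.int(3000)
  g2 <- pmf_2d(cv1[perm], cv2[perm], bins = b)
  expect_equal(g1$G, g2$G)
  # tripling every frame leaves G unchanged
  g3 <- pmf_2d(rep(cv1, 3), rep(cv2, 3), bins = b)
  expect_equal(g1$G, g3$G, tolerance = 1e-12)
})

test_that("basin segmentation finds wells, merges above barriers, is monotone", {
  # constructed two-well landscape on a 1 x 5 strip:
  # counts give G = 0, 1.5, 0.2 pattern -> two basins at cutoff 1.0
  n <- c(1000, 80, 900, 80, 850)
  cv1 <- rep(seq(0.5, 4.5), times = n)
  cv2 <- rep(0.5, sum(n))
  grid <- pmf_2d(cv1, cv2, bins = list(0:5, c(0, 1)))
  seg <- segment_basins(grid, depth_cutoff = 1.0)
  labs <- seg$basins[, 1]
  expect_equal(sum(!is.na(unique(labs))), 3)
  # basins labeled by ascending minimum G: bin 1 (G = 0) is basin 1
  expect_equal(labs[1], 1L)

  # cutoff above the barrier merges everything into one basin
  barrier <- 0.0019872 * 300 * log(1000 / 80)
  seg2 <- segment_basins(grid, depth_cutoff = barrier + 0.1)
  expect_equal(max(seg2$basins, na.rm = TRUE), 1)

  # basin count is monotone non-increasing in the cutoff
  cuts <- c(0.5, 1, 1.5, 2)
  counts <- vapply(cuts, function(ct) {
    max(segment_basins(grid, ct)$basins, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  # frames inherit their bin's basin
  expect_equal(seg$frame_basins$basin[1], 1L)
  expect_true(is.na(seg$frame_basins$basin[1001]))  # barrier bin above cutoff

  expect_error(segment_basins(grid, depth_cutoff = 0), "positive")
})

test_that("landscape modes recover the generator's basin centers", {
  out <- sample_two_state_cv(rbind(c(4, 6), c(9, 11)), 0.3, c(0.7, 0.3),
                             n_frames = 50000, seed = 12)
  grid <- pmf_2d(out$series$cv1, out$series$cv2, bins = 40)
  tt <- tidy(grid)
  top_bin <- tt[which.min(tt$G), ]
  expect_lt(abs(top_bin$cv1 - 4), 0.3)
  expect_lt(abs(top_bin$cv2 - 6), 0.3)
  seg <- segment_basins(grid, 1.0)
  # the two deepest basins sit on the two programmed centers
  tt2 <- tidy(seg)
  b1 <- tt2[!is.na(tt2$basin) & tt2$basin == 1, ]
  b2 <- tt2[!is.na(tt2$basin) & tt2$basin == 2, ]
  expect_lt(abs(mean(b1$cv1) - 4), 0.5)
  expect_lt(abs(mean(b2$cv1) - 9), 0.5)
})

test_that("average-linkage clustering matches a brute-force reference", {
  sys <- build_toy_system(synthetic_spec(n_residues = 5))
  traj <- sample_correlated_trajectory(sys, diag(0.5, 5), 10, seed = 13)$trajectory
  ca <- cluster_average_linkage(traj, n_clusters = 3)
  aligned <- superpose(traj)
  D <- ca$rmsd_matrix
  ref <- avg_linkage_ref(D)
  # merge heights agree with the exhaustive agglomeration
  expect_equal(ca$height, ref$heights, tolerance = 1e-10)
  # partition at k = 3 agrees up to label permutation
  ours <- ca$assignments$cluster
  theirs <- ref$partitions[[3]]
  expect_equal(length(unique(ours)), 3)
  cross <- table(ours, theirs)
  expect_true(all(rowSums(cross > 0) == 1) && all(colSums(cross > 0) == 1))
  # dendrogram heights are monotone non-decreasing
  expect_true(all(diff(ca$height) >= -1e-12))
})

test_that("clustering recovers planted conformers and medoids minimize total RMSD", {
  sys <- build_toy_system(synthetic_spec(n_residues = 5))
  a <- frame_coords(sys, 1)
  b <- a; b[2, ] <- b[2, ] + c(0, 6, 0)   # a distinct rigid conformer
  coords <- array(0, c(5, 3, 8))
  planted <- rep(1:2, 4)
  set.seed(20)
  for (f in 1:8) {
    base <- if (planted[f] == 1) a else b
    coords[, , f] <- base + matrix(rnorm(15, 0, 0.05), 5, 3)
  }
  traj <- md_trajectory(sys$topology, coords)
  ca <- cluster_average_linkage(traj, n_clusters = 2)
  expect_equal(length(unique(ca$assignments$cluster[planted == 1])), 1)
  expect_equal(length(unique(ca$assignments$cluster[planted == 2])), 1)

  # medoid property within each cluster
  for (k in ca$medoids$cluster) {
    members <- ca$assignments$frame[ca$assignments$cluster == k]
    tot <- rowSums(ca$rmsd_matrix[members, members, drop = FALSE])
    med <- ca$medoids$medoid_frame[ca$medoids$cluster == k]
    expect_equal(tot[match(med, members)], min(tot))
  }

  # single cluster: medoid minimizes RMSD to all frames
  ca1 <- cluster_average_linkage(traj, n_clusters = 1)
  tot <- rowSums(ca1$rmsd_matrix)
  expect_equal(ca1$medoids$medoid_frame, which.min(tot))
  expect_error(cluster_average_linkage(traj, n_clusters = 0), "at least 1")
  expect_error(cluster_average_linkage(traj, n_clusters = 9), "exceed")
})
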