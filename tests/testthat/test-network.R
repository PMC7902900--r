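test_that("cross-correlations recover programmed structure at the CLT rate", {
  sys <- build_toy_system(synthetic_spec(n_residues = 6))
  cov <- diag(0.25, 6)
  cov[1, 2] <- cov[2, 1] <- 0.6 * 0.25
  n <- 50000
  traj <- sample_correlated_trajectory(sys, cov, n, seed = 17)$trajectory
  C <- dccm(traj)
  expect_equal(unname(diag(unclass(C))), rep(1, 6))
  expect_lt(abs(unclass(C)[1, 2] - 0.6), 0.02)
  off <- unclass(C)[upper.tri(C)][-1]  # all pairs except (1,2)
  expect_lt(max(abs(off)), 3 / sqrt(n))

  # frame order does not matter
  perm <- sample.int(n)
  C2 <- dccm(subset_frames(traj, perm))
  expect_equal(unclass(C2), unclass(C), tolerance = 1e-12)

  # a rigid collective mode drives correlations toward 1
  drift <- traj
  shift <- 50 * sin(seq_len(n) / 500)
  for (d in 1) drift$coords[, d, ] <-
      sweep(drift$coords[, d, , drop = FALSE], 3, shift, `+`)[, 1, ]
  Cd <- dccm(drift)
  expect_gt(min(unclass(Cd)), 0.95)

  # immobile atoms are named in the error
  frozen <- traj
  frozen$coords[3, , ] <- 0
  expect_error(dccm(frozen), "atom 3")
})

test_that("DCCM masking is strict at the boundary and preserves symmetry", {
  m <- diag(4)
  vals <- c(0.25, 0.299, 0.301, 0.35, -0.25, 0.31)
  k <- 1
  for (i in 1:3) for (j in (i + 1):4) {
    m[i, j] <- m[j, i] <- vals[k]; k <- k + 1
  }
  C <- correlation_matrix(m)
  M <- mask_dccm(C)
  expect_true(is.na(M[1, 2]))           # 0.25 masked
  expect_true(is.na(M[1, 3]))           # 0.299 masked
  expect_false(is.na(M[1, 4]))          # 0.301 kept
  expect_false(is.na(M[2, 3]))          # 0.35 kept
  expect_true(is.na(M[2, 4]))           # -0.25 masked on absolute value
  expect_identical(is.na(unclass(M)), t(is.na(unclass(M))))

  # exact threshold value survives (strict <) and threshold 0 masks nothing
  C3 <- correlation_matrix(rbind(c(1, 0.3), c(0.3, 1)))
  expect_false(is.na(mask_dccm(C3)[1, 2]))
  expect_false(anyNA(mask_dccm(C3, threshold = 0)))
  expect_error(mask_dccm(C3, threshold = 1.5), "0, 1")
})

test_that("network edges obey the persistence and distance gates exactly", {
  sys <- build_toy_system(synthetic_spec(n_residues = 4))
  C <- correlation_matrix(diag(4) * 0 + 0.5 + diag(0.5, 4),
                          nodes = tibble::tibble(node = 1:4, atom = 1:4,
                                                 resid = 1:4, resname = "GLY",
                                                 chain = "A"))
  run <- function(fraction, contact_distance = 4.4) {
    sched <- sample_contact_schedule(
      sys, tibble::tibble(i = 1, j = 3, fraction = fraction),
      contact_distance = contact_distance, apart_distance = 9,
      n_frames = 1000, seed = 23)
    net <- build_network(sched$trajectory, C)
    nrow(net$edges) == 1
  }
  expect_false(run(0.749))
  expect_true(run(0.750))
  expect_true(run(0.751))
  # distance boundary: 4.5 in, 4.51 out (inclusive cutoff)
  expect_true(run(1, contact_distance = 4.5))
  expect_false(run(1, contact_distance = 4.51))

  # weight convention: d = -ln|C|
  sched <- sample_contact_schedule(
    sys, tibble::tibble(i = 1, j = 3, fraction = 1),
    contact_distance = 4, apart_distance = 9, n_frames = 10, seed = 23)
  C1 <- correlation_matrix(diag(4) * 0 + exp(-1) + diag(1 - exp(-1), 4))
  net <- build_network(sched$trajectory, C1)
  expect_equal(net$edges$weight, 1, tolerance = 1e-12)
  Cu <- correlation_matrix(matrix(1, 4, 4))
  expect_equal(build_network(sched$trajectory, Cu)$edges$weight, 0)

  # sequence-adjacent residues never receive an edge
  sched2 <- sample_contact_schedule(
    sys, tibble::tibble(i = 2, j = 3, fraction = 1),
    contact_distance = 4, apart_distance = 9, n_frames = 10, seed = 23)
  expect_equal(nrow(build_network(sched2$trajectory, C)$edges), 0)
})

test_that("community detection splits a two-clique bridge graph", {
  edges <- list()
  for (i in 1:4) for (j in (i + 1):5) edges[[length(edges) + 1]] <- c(i, j)
  for (i in 6:9) for (j in (i + 1):10) edges[[length(edges) + 1]] <- c(i, j)
  em <- do.call(rbind, edges)
  ed <- tibble::tibble(i = c(em[, 1], 5), j = c(em[, 2], 6),
                       weight = log(2), cij = 0.5, persistence = 1)
  net <- dynamic_network(10, ed)
  com <- detect_communities(net)
  expect_equal(com$n_communities, 2)
  split <- split(com$membership$node, com$membership$community)
  expect_setequal(split[[1]], 1:5)
  expect_setequal(split[[2]], 6:10)

  # modularity matches a direct recomputation and beats all-in-one
  expect_equal(com$modularity,
               modularity_ref(net$edges, com$membership$community),
               tolerance = 1e-12)
  expect_gte(com$modularity, modularity_ref(net$edges, rep(1, 10)))

  # brute force over all 2-partitions: no split does better
  best <- -Inf
  for (mask in 1:(2^9 - 1)) {
    memb <- c(1, as.integer(intToBits(mask))[1:9]) + 1
    best <- max(best, modularity_ref(net$edges, memb))
  }
  expect_gte(com$modularity + 1e-12, best)

  # agreement with the established implementation
  g <- as_igraph(net)
  ig <- suppressWarnings(
    igraph::cluster_edge_betweenness(g, weights = igraph::E(g)$weight))
  expect_equal(com$n_communities, length(unique(igraph::membership(ig))))

  # complete graph with uniform weights: a single community
  full <- list()
  for (i in 1:5) for (j in (i + 1):6) full[[length(full) + 1]] <- c(i, j)
  fm <- do.call(rbind, full)
  cfull <- detect_communities(dynamic_network(
    6, tibble::tibble(i = fm[, 1], j = fm[, 2], weight = 1, cij = exp(-1))))
  expect_equal(cfull$n_communities, 1)

  # edgeless graph: singletons with a warning
  expect_warning(
    iso <- detect_communities(dynamic_network(
      3, tibble::tibble(i = integer(), j = integer(), weight = numeric()))),
    "no edges")
  expect_equal(iso$n_communities, 3)
})

test_that("communities separate independently fluctuating domains", {
  out <- two_domain_trajectory(n_frames = 400, seed = 42)
  traj <- out$trajectory
  C <- dccm(traj)
  net <- build_network(traj, C)
  expect_gt(nrow(net$edges), 5)
  com <- detect_communities(net)
  memb <- com$membership$community
  # every residue of a domain shares a label, and the labels differ
  expect_equal(length(unique(memb[1:5])), 1)
  expect_equal(length(unique(memb[6:10])), 1)
  expect_false(memb[1] == memb[10])

  # intercommunity connectivity is positive where a bridge exists
  if (com$n_communities == 2) {
    expect_gte(com$connectivity[1, 2], 0)
  }
})

test_that("optimal and suboptimal paths match exhaustive enumeration", {
  # chain graph: a - b - c
  chain <- dynamic_network(3, tibble::tibble(i = c(1, 2), j = c(2, 3),
                                             weight = c(1, 1)))
  ps <- optimal_paths(chain, 1, 3)
  expect_equal(attr(ps, "l_opt"), 2)
  expect_equal(ps$nodes[[1]], c(1, 2, 3))

  # delta = 0 keeps only exactly-optimal paths
  sq <- dynamic_network(4, tibble::tibble(i = c(1, 1, 2, 3), j = c(2, 3, 4, 4),
                                          weight = c(1, 1, 1, 1.5)))
  ps0 <- optimal_paths(sq, 1, 4, tolerance = 0)
  expect_equal(nrow(ps0), 1)
  expect_equal(ps0$nodes[[1]], c(1, 2, 4))

  # unreachable sink
  disc <- dynamic_network(4, tibble::tibble(i = 1, j = 2, weight = 1))
  expect_error(optimal_paths(disc, 1, 4), "unreachable")

  # 50 random graphs vs brute-force enumeration
  set.seed(31)
  checked <- 0
  while (checked < 50) {
    n <- sample(4:8, 1)
    prob <- runif(1, 0.3, 0.8)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < prob
    if (!any(keep)) next
    ed <- tibble::tibble(i = pairs[keep, 1], j = pairs[keep, 2],
                         weight = round(runif(sum(keep), 0.1, 3), 3))
    net <- dynamic_network(n, ed)
    src <- 1; snk <- n
    ref <- all_simple_paths_ref(n, net$edges, src, snk)
    if (length(ref) == 0) next
    delta <- sample(c(0, 0.5, 2, 20), 1)
    lens <- vapply(ref, function(p) p$length, numeric(1))
    lopt <- min(lens)
    keep_ref <- ref[lens <= lopt + delta + 1e-9]
    ps <- optimal_paths(net, src, snk, tolerance = delta)
    expect_equal(attr(ps, "l_opt"), lopt, tolerance = 1e-12)
    expect_identical(path_keys(ps$nodes),
                     path_keys(lapply(keep_ref, function(p) p$nodes)))
    expect_equal(sort(ps$length),
                 sort(vapply(keep_ref, function(p) p$length, numeric(1))),
                 tolerance = 1e-9)
    # lengths are ascending and within tolerance
    expect_true(all(diff(ps$length) >= -1e-12))
    expect_true(all(ps$length <= lopt + delta + 1e-9))
    checked <- checked + 1
  }

  # Floyd-Warshall distances agree with igraph's shortest paths
  set.seed(77)
  n <- 12
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < 0.4
  ed <- tibble::tibble(i = pairs[keep, 1], j = pairs[keep, 2],
                       weight = runif(sum(keep), 0.1, 2))
  net <- dynamic_network(n, ed)
  g <- as_igraph(net)
  Dref <- igraph::distances(g, weights = igraph::E(g)$weight)
  ours <- trajan:::floyd_warshall(n, ed$i, ed$j, ed$weight)$dist
  expect_equal(unname(ours), unname(Dref), tolerance = 1e-12)

  # suboptimal path count is monotone non-decreasing in the tolerance
  counts <- vapply(c(0, 0.5, 1, 2, 5), function(d) {
    nrow(optimal_paths(net, 1, n, tolerance = d))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
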