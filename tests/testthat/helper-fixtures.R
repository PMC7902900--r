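# Shared fixtures and independent reference implementations ("oracles").

# a parameterised toy complex: nres_rec receptor residues + nres_lig ligand
# residues, one atom each, separated by `gap` Angstrom along x
toy_complex <- function(nres_rec = 2, nres_lig = 1, gap = 5,
                        charges = c(0.4, -0.4, 0.3), radius = 1.9) {
  n <- nres_rec + nres_lig
  top <- md_topology(tibble::tibble(
    name = "CA", element = "C",
    resid = c(seq_len(nres_rec), seq_len(nres_lig)),
    resname = "GLY",
    chain = rep(c("R", "L"), c(nres_rec, nres_lig)),
    charge = rep_len(charges, n), sigma = 3.4, epsilon = 0.1, radius = radius))
  xyz <- cbind(c(3.8 * (seq_len(nres_rec) - 1),
                 3.8 * (seq_len(nres_lig) - 1) + 3.8 * (nres_rec - 1) + gap),
               0, 0)
  md_trajectory(top, xyz)
}

# brute-force average-linkage agglomeration on a distance matrix; returns
# merge heights in order and the membership at each cluster count
avg_linkage_ref <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  membership <- seq_len(n)
  partitions[[n]] <- membership
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (a in seq_len(k - 1)) {
      for (b in seq((a + 1), k)) {
        d <- mean(D[clusters[[a]], clusters[[b]], drop = FALSE])
        if (d < best[1]) best <- c(d, a, b)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
    membership <- integer(n)
    for (ci in seq_along(clusters)) membership[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- membership
  }
  list(heights = heights, partitions = partitions)
}

# exhaustive simple-path enumeration (no pruning) between source and sink
all_simple_paths_ref <- function(n, edges, source, sink) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    adj[[edges$i[k]]] <- rbind(adj[[edges$i[k]]], c(edges$j[k], edges$weight[k]))
    adj[[edges$j[k]]] <- rbind(adj[[edges$j[k]]], c(edges$i[k], edges$weight[k]))
  }
  paths <- list()
  visit <- function(v, len, trail) {
    if (v == sink) {
      paths[[length(paths) + 1]] <<- list(nodes = trail, length = len)
      return()
    }
    nb <- adj[[v]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1]
      if (u %in% trail) next
      visit(u, len + nb[r, 2], c(trail, u))
    }
  }
  visit(source, 0, source)
  paths
}

# canonical string form of a path set for set comparison
path_keys <- function(nodes_list) {
  sort(vapply(nodes_list, paste, character(1), collapse = "-"))
}

# weighted modularity recomputed directly from a partition
modularity_ref <- function(edges, membership, strengths = abs(edges$cij)) {
  W <- sum(strengths)
  if (W <= 0) return(0)
  s <- numeric(max(c(edges$i, edges$j)))
  for (k in seq_along(strengths)) {
    s[edges$i[k]] <- s[edges$i[k]] + strengths[k]
    s[edges$j[k]] <- s[edges$j[k]] + strengths[k]
  }
  q <- sum(strengths[membership[edges$i] == membership[edges$j]]) / W
  for (com in unique(membership)) q <- q - (sum(s[membership == com]) / (2 * W))^2
  q
}

# two-domain fixture: 5+5 residues on two small spheres with one facing
# contact pair (residues 5 and 7 at 4.2 A), block-structured correlations
two_domain_trajectory <- function(n_frames = 400, rho_in = 0.9, rho_out = 0.1,
                                  sigma2 = 0.04, seed = 42) {
  offsets <- rbind(c(-2, 0, 0), c(0, 2, 0), c(0, 0, 2), c(0, -2, 0), c(2, 0, 0))
  xyz <- rbind(offsets,
               rbind(c(0, 2, 0), c(-2, 0, 0), c(0, 0, 2), c(0, -2, 0),
                     c(2, 0, 0)) + matrix(rep(c(8.2, 0, 0), each = 5), 5))
  top <- md_topology(tibble::tibble(
    name = "CA", element = "C", resid = 1:10, resname = "GLY", chain = "A",
    charge = 0, sigma = 3.4, epsilon = 0.1, radius = 1.9))
  sys <- md_trajectory(top, xyz)
  block <- matrix(rho_out, 10, 10)
  block[1:5, 1:5] <- rho_in
  block[6:10, 6:10] <- rho_in
  diag(block) <- 1
  sample_correlated_trajectory(sys, sigma2 * block, n_frames, seed = seed)
}
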