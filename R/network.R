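#' Dynamic cross-correlation matrix
#'
#' Normalized covariance of atomic displacement vectors,
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)` with deviations taken
#' about each atom's time-mean position.  The trajectory should be
#' superposed (global fit) first so rigid-body motion does not masquerade
#' as correlation.
#'
#' @param traj An aligned [md_trajectory] with at least 2 frames.
#' @param selection Atom indices (typically one C-alpha per residue);
#'   default all atoms.
#' @return Symmetric matrix of class `dccm` with unit diagonal; the
#'   node-to-residue mapping is attached as attribute `"nodes"`.
#' @export
dccm <- function(traj, selection = NULL) {
  if (n_frames(traj) < 2) abort("correlations need at least 2 frames")
  N <- n_atoms(traj)
  sel <- if (is.null(selection)) seq_len(N) else check_selection(selection, N)
  cs <- traj$coords[sel, , , drop = FALSE]
  FF <- dim(cs)[3]
  S <- matrix(0, length(sel), length(sel))
  for (d in 1:3) {
    X <- t(matrix(cs[, d, ], length(sel), FF))  # frames x atoms
    Xc <- sweep(X, 2, colMeans(X))
    S <- S + crossprod(Xc) / FF
  }
  v <- diag(S)
  scale <- max(v, 1e-300)
  if (any(v < 1e-12 * scale)) {
    bad <- sel[which(v < 1e-12 * scale)[1]]
    abort(paste0("undefined correlation: atom ", traj$topology$atom_id[bad],
                 " has zero displacement variance"))
  }
  C <- S / sqrt(outer(v, v))
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  top <- traj$topology[sel, ]
  attr(C, "nodes") <- tibble(node = seq_along(sel), atom = sel,
                             resid = top$resid, resname = top$resname,
                             chain = top$chain)
  class(C) <- c("dccm", class(C))
  C
}

#' Construct a correlation matrix object from explicit values
#'
#' Wraps a symmetric matrix with unit diagonal (values in `[-1, 1]`) in the
#' same class [dccm()] produces, attaching a node mapping, so that
#' downstream network construction can be driven by externally supplied or
#' programmed correlations.
#'
#' @param C Symmetric numeric matrix, unit diagonal, entries in `[-1, 1]`.
#' @param nodes Optional tibble with one row per node (`node`, `resid`,
#'   `chain`, ...); defaults to node = resid = row number, chain "A".
#' @return A `dccm` matrix.
#' @export
correlation_matrix <- function(C, nodes = NULL) {
  C <- as.matrix(C)
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-10))) abort("C must be symmetric")
  if (any(abs(C) > 1 + 1e-12)) abort("correlations must lie in [-1, 1]")
  if (any(abs(diag(C) - 1) > 1e-12)) abort("diagonal must be exactly 1")
  if (is.null(nodes)) {
    nodes <- tibble(node = seq_len(nrow(C)), atom = seq_len(nrow(C)),
                    resid = seq_len(nrow(C)),
                    resname = "GLY", chain = "A")
  }
  attr(C, "nodes") <- as_tibble(nodes)
  class(C) <- c("dccm", class(C))
  C
}

#' Construct a dynamic network from explicit node and edge tables
#'
#' Mainly useful for programmatic graphs (method verification, boundary
#' scans); [build_network()] is the data-driven route.
#'
#' @param n_nodes Number of nodes, or a nodes tibble.
#' @param edges Tibble with columns `i`, `j` and `weight` (and optionally
#'   `cij`, `persistence`).
#' @return A `dynamic_network`.
#' @export
dynamic_network <- function(n_nodes, edges) {
  nodes <- if (is.data.frame(n_nodes)) as_tibble(n_nodes) else
    tibble(node = seq_len(n_nodes), atom = seq_len(n_nodes),
           resid = seq_len(n_nodes), resname = "GLY", chain = "A")
  edges <- as_tibble(edges)
  if (!all(c("i", "j", "weight") %in% names(edges))) {
    abort("edges need columns i, j, weight")
  }
  if (nrow(edges)) {
    if (any(edges$i == edges$j)) abort("self-edges are not allowed")
    if (any(edges$weight < 0)) abort("edge weights must be non-negative")
    swap <- edges$i > edges$j
    tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
    if (!"cij" %in% names(edges)) edges$cij <- exp(-edges$weight)
    if (!"persistence" %in% names(edges)) edges$persistence <- 1
  } else {
    if (!"cij" %in% names(edges)) edges$cij <- numeric()
    if (!"persistence" %in% names(edges)) edges$persistence <- numeric()
  }
  structure(list(nodes = nodes, edges = edges, contact_cutoff = NA_real_,
                 persistence_threshold = NA_real_),
            class = "dynamic_network")
}

#' Mask weak correlations for display
#'
#' Entries with `|C| < threshold` (strict inequality: the threshold value
#' itself survives) are set to `NA`; symmetry is preserved.
#'
#' @param C A correlation matrix (e.g. from [dccm()]).
#' @param threshold Masking boundary in `[0, 1]`; default 0.3.
#' @return The matrix with sub-threshold entries `NA`.
#' @export
mask_dccm <- function(C, threshold = 0.3) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    abort("threshold must lie in [0, 1]")
  }
  out <- unclass(C)
  out[abs(out) < threshold] <- NA_real_
  attributes(out) <- attributes(C)
  out
}

#' Build a persistence-gated dynamic network
#'
#' Residues are nodes (positioned at their C-alpha).  An edge joins
#' residues i and j when their minimum heavy-atom distance is within
#' `contact_cutoff` (inclusive) for at least a `persistence` fraction of
#' frames (inclusive) and the residues are not sequence-adjacent.  Edge
#' weights are `d_ij = -ln |C_ij|` with `|C|` floored at 1e-6.
#'
#' @param traj An [md_trajectory].
#' @param C A [dccm()] over one node atom per residue.
#' @param contact_cutoff Contact distance cutoff, Angstrom (default 4.5).
#' @param persistence Minimum contact fraction for an edge (default 0.75).
#' @return Object of class `dynamic_network`: list with `nodes` and
#'   `edges` tibbles.
#' @export
build_network <- function(traj, C, contact_cutoff = 4.5, persistence = 0.75) {
  nodes <- attr(C, "nodes")
  if (is.null(nodes)) abort("C must carry a node mapping (build it with dccm())")
  top <- traj$topology
  reskey <- paste(top$chain, top$resid)
  nodekey <- paste(nodes$chain, nodes$resid)
  # atoms of residues not listed in C do not carry contacts
  resindex <- match(reskey, nodekey)
  use <- !is.na(resindex) & top$element != "H"
  if (!any(use)) abort("no heavy atoms map onto the network nodes")
  frac <- contact_fraction_matrix(traj$coords, as.integer(resindex) - 1L,
                                  use, nrow(nodes), contact_cutoff)
  n <- nrow(nodes)
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      adjacent <- nodes$chain[i] == nodes$chain[j] &&
        abs(nodes$resid[i] - nodes$resid[j]) <= 1
      if (adjacent) next
      if (frac[i, j] >= persistence) {
        cij <- unclass(C)[i, j]
        edges[[length(edges) + 1]] <- tibble(
          i = i, j = j, persistence = frac[i, j], cij = cij,
          weight = -log(max(abs(cij), 1e-6)))
      }
    }
  }
  edges <- if (length(edges)) bind_rows(edges) else
    tibble(i = integer(), j = integer(), persistence = numeric(),
           cij = numeric(), weight = numeric())
  structure(list(nodes = nodes, edges = edges,
                 contact_cutoff = contact_cutoff,
                 persistence_threshold = persistence),
            class = "dynamic_network")
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat("<dynamic_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (cutoff ", x$contact_cutoff, " A, persistence >= ",
      x$persistence_threshold, ")\n", sep = "")
  invisible(x)
}

#' Convert a dynamic network to an igraph graph
#' @param net A [build_network()] result.
#' @return An igraph object with edge attribute `weight` (the -ln|C|
#'   length) and `cij`.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(net$edges$i, net$edges$j))
    igraph::E(g)$weight <- net$edges$weight
    igraph::E(g)$cij <- net$edges$cij
  }
  igraph::V(g)$name <- as.character(seq_len(nrow(net$nodes)))
  g
}

# weighted modularity of a partition; w = edge strengths
modularity_of <- function(edges_i, edges_j, w, membership, n) {
  W <- sum(w)
  if (W <= 0) return(0)
  strength <- numeric(n)
  for (k in seq_along(w)) {
    strength[edges_i[k]] <- strength[edges_i[k]] + w[k]
    strength[edges_j[k]] <- strength[edges_j[k]] + w[k]
  }
  same <- membership[edges_i] == membership[edges_j]
  q <- sum(w[same]) / W
  for (com in unique(membership)) {
    s <- sum(strength[membership == com])
    q <- q - (s / (2 * W))^2
  }
  q
}

#' Community detection by divisive edge betweenness (Girvan-Newman)
#'
#' Edges are removed in order of highest shortest-path betweenness
#' (shortest paths measured with the `-ln|C|` weights as lengths; ties
#' broken by lexicographic edge order); among the nested partitions the one
#' maximizing weighted modularity (strengths `|C_ij|`) is returned.
#' Intercommunity connectivity is the summed betweenness (computed on the
#' full network) of the edges joining each pair of communities.
#'
#' @param net A [build_network()] result.
#' @return Object of class `community_partition`: `membership` tibble,
#'   `modularity`, `n_communities`, and the `connectivity` matrix.
#' @export
detect_communities <- function(net) {
  n <- nrow(net$nodes)
  if (n == 0) abort("network has no nodes")
  ed <- net$edges
  if (nrow(ed) == 0) {
    warn("network has no edges: every node forms its own community")
    membership <- seq_len(n)
    return(structure(list(
      membership = tibble(node = seq_len(n), resid = net$nodes$resid,
                          chain = net$nodes$chain, community = membership),
      modularity = 0, n_communities = n,
      connectivity = matrix(0, n, n)), class = "community_partition"))
  }
  strengths <- abs(ed$cij)
  # betweenness on the intact network, for intercommunity connectivity
  g_full <- as_igraph(net)
  bt_full <- igraph::edge_betweenness(g_full, weights = igraph::E(g_full)$weight)

  # divisive loop over a shrinking edge set
  live <- rep(TRUE, nrow(ed))
  best <- NULL
  repeat {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (any(live)) {
      g <- igraph::add_edges(g, rbind(ed$i[live], ed$j[live]))
    }
    memb <- igraph::components(g)$membership
    q <- modularity_of(ed$i, ed$j, strengths, memb, n)
    if (is.null(best) || q > best$q + 1e-12) best <- list(q = q, membership = memb)
    if (!any(live)) break
    bt <- igraph::edge_betweenness(g, weights = ed$weight[live])
    live_idx <- which(live)
    mx <- max(bt)
    cand <- live_idx[bt >= mx - 1e-12 * max(mx, 1)]
    # lexicographic (i, j) tie-break for determinism
    pick <- cand[order(ed$i[cand], ed$j[cand])][1]
    live[pick] <- FALSE
  }
  memb <- as.integer(factor(best$membership, levels = unique(best$membership)))
  ncom <- max(memb)
  conn <- matrix(0, ncom, ncom)
  for (k in seq_len(nrow(ed))) {
    a <- memb[ed$i[k]]; b <- memb[ed$j[k]]
    if (a != b) {
      conn[a, b] <- conn[a, b] + bt_full[k]
      conn[b, a] <- conn[a, b]
    }
  }
  structure(list(
    membership = tibble(node = seq_len(n), resid = net$nodes$resid,
                        chain = net$nodes$chain, community = memb),
    modularity = best$q, n_communities = ncom, connectivity = conn),
    class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("<community_partition> ", x$n_communities, " communities, modularity ",
      round(x$modularity, 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.community_partition <- function(x, ...) x$membership

#' @export
glance.community_partition <- function(x, ...) {
  tibble(n_communities = x$n_communities, modularity = x$modularity,
         n_nodes = nrow(x$membership))
}

# Floyd-Warshall all-pairs shortest distances with path reconstruction.
# Returns list(dist, nxt) where nxt[i, j] is the next node after i on a
# shortest i -> j path (NA if unreachable).
floyd_warshall <- function(n, edges_i, edges_j, w) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  nxt <- matrix(NA_integer_, n, n)
  for (k in seq_along(w)) {
    i <- edges_i[k]; j <- edges_j[k]
    if (w[k] < D[i, j]) {
      D[i, j] <- w[k]; D[j, i] <- w[k]
      nxt[i, j] <- j; nxt[j, i] <- i
    }
  }
  diag(nxt) <- seq_len(n)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      dik <- D[i, k]
      if (!is.finite(dik)) next
      better <- dik + D[k, ] < D[i, ]
      if (any(better)) {
        D[i, better] <- dik + D[k, better]
        nxt[i, better] <- nxt[i, k]
      }
    }
  }
  list(dist = D, nxt = nxt)
}

#' Optimal and suboptimal paths between two network nodes
#'
#' All-pairs shortest distances come from the Floyd-Warshall algorithm;
#' the optimal path is reconstructed from it, and every simple path whose
#' summed edge weight is within `tolerance` of the optimal length is
#' enumerated by depth-first search pruned with the exact
#' distances-to-sink.
#'
#' @param net A [build_network()] result.
#' @param source,sink Node indices (1-based, distinct).
#' @param tolerance Suboptimal length tolerance in edge-weight units
#'   (default 20).
#' @param max_paths Safety cap on the number of enumerated paths.
#' @return Object of class `path_set`: tibble of paths sorted by ascending
#'   length (`path_id`, `length`, `nodes` list-column), with `l_opt`,
#'   `tolerance`, `source`, `sink` attributes.
#' @export
optimal_paths <- function(net, source, sink, tolerance = 20,
                          max_paths = 100000) {
  n <- nrow(net$nodes)
  source <- as.integer(source); sink <- as.integer(sink)
  if (source == sink) abort("source and sink must differ")
  if (source < 1 || source > n || sink < 1 || sink > n) abort("node out of range")
  if (tolerance < 0) abort("tolerance must be non-negative")
  ed <- net$edges
  fw <- floyd_warshall(n, ed$i, ed$j, ed$weight)
  l_opt <- fw$dist[source, sink]
  if (!is.finite(l_opt)) {
    abort("sink is unreachable from source (different components)")
  }
  # adjacency with weights
  adj <- vector("list", n)
  for (k in seq_len(nrow(ed))) {
    adj[[ed$i[k]]] <- rbind(adj[[ed$i[k]]], c(ed$j[k], ed$weight[k]))
    adj[[ed$j[k]]] <- rbind(adj[[ed$j[k]]], c(ed$i[k], ed$weight[k]))
  }
  # deterministic neighbour order
  for (v in seq_len(n)) {
    if (!is.null(adj[[v]])) adj[[v]] <- adj[[v]][order(adj[[v]][, 1]), , drop = FALSE]
  }
  limit <- l_opt + tolerance + 1e-9
  dist_to_sink <- fw$dist[, sink]
  paths <- list()
  overflow <- FALSE
  on_path <- rep(FALSE, n)
  dfs <- function(v, len, trail) {
    if (overflow) return()
    if (v == sink) {
      paths[[length(paths) + 1]] <<- list(nodes = trail, length = len)
      if (length(paths) >= max_paths) overflow <<- TRUE
      return()
    }
    nb <- adj[[v]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1]; wl <- nb[r, 2]
      if (on_path[u]) next
      if (len + wl + dist_to_sink[u] > limit) next
      on_path[u] <<- TRUE
      dfs(u, len + wl, c(trail, u))
      on_path[u] <<- FALSE
    }
  }
  on_path[source] <- TRUE
  dfs(source, 0, source)
  if (overflow) {
    warn(paste0("path enumeration truncated at ", max_paths, " paths"))
  }
  lens <- vapply(paths, function(p) p$length, numeric(1))
  ord <- order(lens, vapply(paths, function(p) paste(sprintf("%06d", p$nodes),
                                                     collapse = "-"), character(1)))
  out <- tibble(path_id = seq_along(ord),
                length = lens[ord],
                nodes = lapply(paths[ord], function(p) p$nodes))
  structure(out, l_opt = l_opt, tolerance = tolerance, source = source,
            sink = sink, class = c("path_set", class(out)))
}

#' @export
print.path_set <- function(x, ...) {
  cat("<path_set> ", nrow(x), " path(s) from ", attr(x, "source"), " to ",
      attr(x, "sink"), "; optimal length ", round(attr(x, "l_opt"), 4),
      ", tolerance ", attr(x, "tolerance"), "\n", sep = "")
  NextMethod()
}

#' @export
tidy.path_set <- function(x, ...) {
  tibble(path_id = x$path_id, length = x$length,
         n_nodes = vapply(x$nodes, length, integer(1)),
         path = vapply(x$nodes, paste, character(1), collapse = "-"))
}

#' @export
glance.path_set <- function(x, ...) {
  tibble(n_paths = nrow(x), l_opt = attr(x, "l_opt"),
         tolerance = attr(x, "tolerance"),
         source = attr(x, "source"), sink = attr(x, "sink"))
}
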