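#' Two-dimensional potential of mean force over collective variables
#'
#' Bins the joint (cv1, cv2) distribution and converts occupancies to free
#' energies, `G = -kB * T * ln(n_bin / n_max)` (kB = 0.0019872
#' kcal/mol/K), so the most-occupied bin sits at G = 0.  Empty bins are
#' `NA` (undefined), never zero.
#'
#' @param cv1,cv2 Equal-length numeric per-frame series (Angstrom), or
#'   columns of the tibble returned by [sample_two_state_cv()].
#' @param bins Number of bins per axis (default 50) spanning the observed
#'   range padded by 5 percent of the span on each side; or a list of two
#'   explicit break vectors.
#' @param temperature Temperature in Kelvin (default 300).
#' @return An object of class `pmf_grid`: list with `breaks1`, `breaks2`,
#'   `counts`, `G`, `temperature`, and the per-frame bin assignment.
#' @export
pmf_2d <- function(cv1, cv2, bins = 50, temperature = 300) {
  cv1 <- as.numeric(cv1); cv2 <- as.numeric(cv2)
  if (length(cv1) == 0) abort("empty collective-variable input")
  if (length(cv1) != length(cv2)) abort("cv1 and cv2 must have equal length")
  if (!all(is.finite(cv1)) || !all(is.finite(cv2))) abort("CV series must be finite")
  pad_breaks <- function(x, nb) {
    span <- max(x) - min(x)
    pad <- if (span > 0) 0.05 * span else 0.5
    seq(min(x) - pad, max(x) + pad, length.out = nb + 1)
  }
  if (is.list(bins)) {
    b1 <- bins[[1]]; b2 <- bins[[2]]
  } else {
    b1 <- pad_breaks(cv1, bins); b2 <- pad_breaks(cv2, bins)
  }
  ix <- findInterval(cv1, b1, rightmost.closed = TRUE)
  iy <- findInterval(cv2, b2, rightmost.closed = TRUE)
  n1 <- length(b1) - 1; n2 <- length(b2) - 1
  keep <- ix >= 1 & ix <= n1 & iy >= 1 & iy <= n2
  counts <- matrix(0L, n1, n2)
  tab <- table(factor(ix[keep], levels = seq_len(n1)),
               factor(iy[keep], levels = seq_len(n2)))
  counts[] <- as.integer(tab)
  if (all(counts == 0)) abort("no occupied bins")
  G <- matrix(NA_real_, n1, n2)
  occ <- counts > 0
  G[occ] <- -KB_KCAL * temperature * log(counts[occ] / max(counts))
  structure(list(breaks1 = b1, breaks2 = b2, counts = counts, G = G,
                 temperature = temperature,
                 frame_bins = tibble(frame = seq_along(cv1),
                                     ix = ifelse(keep, ix, NA_integer_),
                                     iy = ifelse(keep, iy, NA_integer_)),
                 basins = NULL),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat("<pmf_grid> ", nrow(x$counts), " x ", ncol(x$counts), " bins, ",
      sum(x$counts), " frames, T = ", x$temperature, " K",
      if (!is.null(x$basins)) paste0(", ", max(0, x$basins, na.rm = TRUE), " basin(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Free-energy grid as a tidy tibble
#' @param x A `pmf_grid`.
#' @param ... Unused.
#' @return Tibble with bin centers `cv1`, `cv2`, `count`, `G`, and `basin`
#'   when segmented.
#' @export
tidy.pmf_grid <- function(x, ...) {
  m1 <- (head(x$breaks1, -1) + tail(x$breaks1, -1)) / 2
  m2 <- (head(x$breaks2, -1) + tail(x$breaks2, -1)) / 2
  out <- tibble(cv1 = rep(m1, times = length(m2)),
                cv2 = rep(m2, each = length(m1)),
                count = as.vector(x$counts),
                G = as.vector(x$G))
  if (!is.null(x$basins)) out$basin <- as.vector(x$basins)
  out
}

#' @export
glance.pmf_grid <- function(x, ...) {
  tibble(n_frames = sum(x$counts), n_bins_occupied = sum(x$counts > 0),
         max_G = max(x$G, na.rm = TRUE), temperature = x$temperature,
         n_basins = if (is.null(x$basins)) NA_integer_ else
           max(0L, x$basins, na.rm = TRUE))
}

#' Segment a free-energy landscape into basins
#'
#' Basins are the connected components (4-neighborhood) of occupied bins
#' with `G <= depth_cutoff`, labeled in ascending order of their minimum
#' free energy.  Frames inherit their bin's basin; frames in bins above the
#' cutoff (or empty bins) are unassigned (`NA`).
#'
#' @param grid A [pmf_2d()] grid.
#' @param depth_cutoff Free-energy cutoff in kcal/mol (> 0); default 1.0.
#' @return The grid with `basins` (matrix of labels, `NA` outside basins)
#'   and `frame_basins` (tibble `frame`, `basin`) filled in.
#' @export
segment_basins <- function(grid, depth_cutoff = 1.0) {
  if (!inherits(grid, "pmf_grid")) abort("grid must be a pmf_grid")
  if (!is.numeric(depth_cutoff) || depth_cutoff <= 0) {
    abort("depth_cutoff must be a positive free energy (kcal/mol)")
  }
  G <- grid$G
  n1 <- nrow(G); n2 <- ncol(G)
  in_basin <- !is.na(G) & G <= depth_cutoff
  labels <- matrix(NA_integer_, n1, n2)
  comp <- 0L
  for (start in which(in_basin)) {
    if (!is.na(labels[start])) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1) %% n1 + 1; j <- (cur - 1) %/% n1 + 1
      for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        if (nb[1] < 1 || nb[1] > n1 || nb[2] < 1 || nb[2] > n2) next
        lin <- (nb[2] - 1) * n1 + nb[1]
        if (in_basin[lin] && is.na(labels[lin])) {
          labels[lin] <- comp
          queue <- c(queue, lin)
        }
      }
    }
  }
  # relabel by ascending minimum G (ties by first occurrence)
  if (comp > 0) {
    minG <- vapply(seq_len(comp), function(k) min(G[which(labels == k)]), numeric(1))
    ord <- order(minG, seq_len(comp))
    relab <- integer(comp); relab[ord] <- seq_len(comp)
    labels[!is.na(labels)] <- relab[labels[!is.na(labels)]]
  }
  grid$basins <- labels
  fb <- grid$frame_bins
  lin <- (fb$iy - 1) * n1 + fb$ix
  basin <- rep(NA_integer_, nrow(fb))
  okf <- !is.na(lin)
  basin[okf] <- labels[lin[okf]]
  grid$frame_basins <- tibble(frame = fb$frame, basin = basin)
  grid
}

#' Average-linkage conformational clustering with representative structures
#'
#' Frames are superposed on the selection (reference: first frame), the
#' pairwise RMSD matrix over the selection is clustered by agglomerative
#' average linkage, and the tree is cut at `n_clusters`.  Each cluster's
#' representative (medoid) is the member frame minimizing the summed RMSD
#' to all other members (ties broken by lowest frame index).
#'
#' @param traj An [md_trajectory].
#' @param selection Atom indices used for superposition and RMSD (default
#'   all atoms).
#' @param n_clusters Number of clusters (1 <= n_clusters <= frames).
#' @return Object of class `cluster_assignment`: list with `assignments`
#'   (tibble `frame`, `cluster`), `medoids` (tibble `cluster`,
#'   `medoid_frame`, `n_members`), `merge`, `height` (average-linkage merge
#'   history) and the RMSD matrix.
#' @export
cluster_average_linkage <- function(traj, selection = NULL, n_clusters) {
  FF <- n_frames(traj)
  if (n_clusters < 1) abort("n_clusters must be at least 1")
  if (n_clusters > FF) abort("n_clusters cannot exceed the frame count")
  sel <- if (is.null(selection)) seq_len(n_atoms(traj)) else
    check_selection(selection, n_atoms(traj))
  aligned <- superpose(traj, reference = 1, selection = sel)
  D <- pairwise_rmsd_matrix(aligned$coords[sel, , , drop = FALSE])
  hc <- hclust(as.dist(D), method = "average")
  cl <- cutree(hc, k = n_clusters)
  medoids <- vapply(sort(unique(cl)), function(k) {
    members <- which(cl == k)
    if (length(members) == 1) return(members)
    tot <- rowSums(D[members, members, drop = FALSE])
    members[which.min(tot)]  # which.min takes the first = lowest frame index
  }, integer(1))
  structure(list(
    assignments = tibble(frame = seq_len(FF), cluster = as.integer(cl)),
    medoids = tibble(cluster = sort(unique(cl)), medoid_frame = medoids,
                     n_members = as.integer(table(cl)[as.character(sort(unique(cl)))])),
    merge = hc$merge, height = hc$height, rmsd_matrix = D),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", nrow(x$assignments), " frames in ",
      nrow(x$medoids), " cluster(s)\n", sep = "")
  print(x$medoids)
  invisible(x)
}

#' @export
tidy.cluster_assignment <- function(x, ...) x$assignments

#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble(n_frames = nrow(x$assignments), n_clusters = nrow(x$medoids),
         largest_cluster = max(x$medoids$n_members))
}
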