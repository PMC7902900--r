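#' Per-frame distances and angles
#'
#' Evaluates Euclidean distances (Angstrom) and planar angles (degrees,
#' vertex at the middle atom) for every frame.  An angle whose three points
#' include coincident atoms in some frame is returned as `NA` for that frame
#' with `defined = FALSE` and a warning — never silently dropped.
#'
#' @param traj An [md_trajectory].
#' @param distances Two-column matrix (or list of length-2 vectors) of atom
#'   indices.
#' @param angles Three-column matrix (or list of length-3 vectors) of atom
#'   indices; the angle is measured at the middle atom.
#' @param labels Optional character labels, distances first then angles.
#' @return Tibble with columns `frame`, `label`, `type`, `value`, `defined`.
#' @export
geometry_series <- function(traj, distances = NULL, angles = NULL, labels = NULL) {
  as_idx_mat <- function(x, k) {
    if (is.null(x)) return(NULL)
    m <- if (is.list(x)) do.call(rbind, x) else rbind(x)
    if (ncol(m) != k) abort(paste0("definitions must have ", k, " atom indices"))
    storage.mode(m) <- "integer"
    m
  }
  dm <- as_idx_mat(distances, 2); am <- as_idx_mat(angles, 3)
  N <- n_atoms(traj)
  idx <- c(dm, am)
  if (length(idx) == 0) abort("no distance or angle definitions supplied")
  if (any(idx < 1 | idx > N)) abort("atom index out of range in geometry definition")
  n_def <- (if (is.null(dm)) 0 else nrow(dm)) + (if (is.null(am)) 0 else nrow(am))
  if (is.null(labels)) {
    labels <- c(
      if (!is.null(dm)) sprintf("d_%d_%d", dm[, 1], dm[, 2]),
      if (!is.null(am)) sprintf("a_%d_%d_%d", am[, 1], am[, 2], am[, 3]))
  }
  if (length(labels) != n_def) abort("one label per definition is required")

  FF <- n_frames(traj)
  out <- vector("list", n_def)
  k <- 0
  atom_xyz <- function(i) matrix(traj$coords[i, , ], 3, FF)
  if (!is.null(dm)) {
    for (r in seq_len(nrow(dm))) {
      k <- k + 1
      d <- sqrt(colSums((atom_xyz(dm[r, 1]) - atom_xyz(dm[r, 2]))^2))
      out[[k]] <- tibble(frame = seq_len(FF), label = labels[k],
                         type = "distance", value = d, defined = TRUE)
    }
  }
  if (!is.null(am)) {
    for (r in seq_len(nrow(am))) {
      k <- k + 1
      v1 <- atom_xyz(am[r, 1]) - atom_xyz(am[r, 2])
      v2 <- atom_xyz(am[r, 3]) - atom_xyz(am[r, 2])
      n1 <- sqrt(colSums(v1^2)); n2 <- sqrt(colSums(v2^2))
      bad <- n1 < 1e-12 | n2 < 1e-12
      cosang <- colSums(v1 * v2) / pmax(n1 * n2, 1e-300)
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      ang[bad] <- NA_real_
      if (any(bad)) {
        warn(paste0("angle ", labels[k], " undefined (coincident atoms) in ",
                    sum(bad), " frame(s)"))
      }
      out[[k]] <- tibble(frame = seq_len(FF), label = labels[k],
                         type = "angle", value = ang, defined = !bad)
    }
  }
  bind_rows(out)
}

#' Probability-density histograms of geometry series
#'
#' @param series Output of [geometry_series()] (or any tibble with `label`
#'   and `value`).
#' @param bin_width Bin width in the series' units (default 0.1).
#' @return Tibble with `label`, `mid`, `count`, `density`.
#' @export
geometry_histogram <- function(series, bin_width = 0.1) {
  if (bin_width <= 0) abort("bin_width must be positive")
  series %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$label) %>%
    group_modify_hist(bin_width)
}

group_modify_hist <- function(grouped, bin_width) {
  dplyr::group_modify(grouped, function(df, key) {
    lo <- floor(min(df$value) / bin_width) * bin_width
    hi <- ceiling(max(df$value) / bin_width + 1e-9) * bin_width
    breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
    h <- graphics::hist(df$value, breaks = breaks, plot = FALSE)
    tibble(mid = h$mids, count = h$counts, density = h$density)
  }) %>% ungroup()
}

# charged-group heavy atoms per residue type for salt-bridge geometry
SALT_BRIDGE_ATOMS <- list(
  acidic = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                PTR = c("O1P", "O2P", "O3P")),
  basic = list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
               HIS = c("ND1", "NE2"), HIE = c("ND1", "NE2"),
               HID = c("ND1", "NE2"), HIP = c("ND1", "NE2"))
)

#' Contact / salt-bridge persistence over a trajectory
#'
#' For each residue pair the fraction of frames (inclusive `<=` cutoff) in
#' which the pair is in contact.  In `"atom-pair"` mode the distance is the
#' minimum over all heavy atoms of the two residues; in `"salt-bridge"` mode
#' one residue must be acidic (Asp/Glu/pTyr) and one basic (Lys/Arg/His) and
#' the distance is the minimum over their charged-group heavy atoms.
#'
#' @param traj An [md_trajectory].
#' @param pairs Data frame (or 2-column matrix) of residue index pairs
#'   `i`, `j`.
#' @param cutoff Contact cutoff in Angstrom (inclusive).  Default 4.0.
#' @param mode `"atom-pair"` or `"salt-bridge"`.
#' @return Tibble with `i`, `j`, `n_contact`, `fraction`; the per-frame
#'   minimum distances are attached as attribute `"distances"` (tibble with
#'   `frame`, `pair`, `distance`).
#' @export
persistence_table <- function(traj, pairs, cutoff = 4.0,
                              mode = c("atom-pair", "salt-bridge")) {
  mode <- match.arg(mode)
  if (is.matrix(pairs)) pairs <- tibble(i = pairs[, 1], j = pairs[, 2])
  pairs <- as_tibble(pairs)
  top <- traj$topology
  FF <- n_frames(traj)

  group_atoms <- function(res, role) {
    rows <- which(top$resid == res)
    if (!length(rows)) abort(paste0("residue ", res, " not in topology"))
    if (mode == "atom-pair") {
      return(rows[top$element[rows] != "H"])
    }
    rn <- top$resname[rows][1]
    tab <- SALT_BRIDGE_ATOMS[[role]]
    if (!rn %in% names(tab)) {
      abort(paste0("residue ", res, " (", rn, ") is not ", role,
                   "; cannot define a salt bridge"))
    }
    out <- rows[top$name[rows] %in% tab[[rn]]]
    if (!length(out)) {
      abort(paste0("residue ", res, " (", rn, ") lacks charged-group atoms"))
    }
    out
  }

  res <- vector("list", nrow(pairs))
  dists <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    ri <- pairs$i[p]; rj <- pairs$j[p]
    if (mode == "salt-bridge") {
      rn_i <- top$resname[top$resid == ri][1]
      acidic_first <- rn_i %in% names(SALT_BRIDGE_ATOMS$acidic)
      ai <- group_atoms(ri, if (acidic_first) "acidic" else "basic")
      aj <- group_atoms(rj, if (acidic_first) "basic" else "acidic")
    } else {
      ai <- group_atoms(ri, NULL); aj <- group_atoms(rj, NULL)
    }
    dmin <- min_pair_dist_series(traj$coords, ai, aj)
    k <- sum(dmin <= cutoff)
    res[[p]] <- tibble(i = ri, j = rj, n_contact = k, fraction = k / FF)
    dists[[p]] <- tibble(frame = seq_len(FF), pair = paste0(ri, "-", rj),
                         distance = dmin)
  }
  out <- bind_rows(res)
  attr(out, "distances") <- bind_rows(dists)
  out
}

# per-frame minimum distance between two atom groups
min_pair_dist_series <- function(coords, ai, aj) {
  FF <- dim(coords)[3]
  vapply(seq_len(FF), function(f) {
    A <- matrix(coords[ai, , f], length(ai), 3)
    B <- matrix(coords[aj, , f], length(aj), 3)
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    sqrt(max(min(d2), 0))
  }, numeric(1))
}

#' Welch's unequal-variance two-sample t test
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @return Tibble with `estimate` (mean difference a - b), `statistic` (t),
#'   `parameter` (Welch-Satterthwaite degrees of freedom) and `p.value`
#'   (two-sided).
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) abort("both samples need at least 2 values")
  va <- var(a); vb <- var(b); na <- length(a); nb <- length(b)
  if (va <= 0 && vb <= 0) abort("undefined statistic: both samples have zero variance")
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  tibble(estimate = mean(a) - mean(b), statistic = t, parameter = df,
         p.value = 2 * pt(-abs(t), df))
}
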