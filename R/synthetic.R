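#' Specification for a synthetic toy molecular system
#'
#' Describes a small protein-like system with one node-defining
#' "C-alpha-like" atom per residue plus optional extra atoms, and per-atom
#' parameters.  Default parameter magnitudes are protein-like (charge 0 e,
#' sigma 3.4 A, epsilon 0.1 kcal/mol, radius 1.9 A) so that
#' Lennard-Jones/Poisson-Boltzmann arithmetic stays well conditioned.
#'
#' @param n_residues Total residue count (>= 1); ignored when `chain_layout`
#'   is given.
#' @param atoms_per_residue Atoms per residue (>= 1); the first is the
#'   C-alpha-like node atom named `"CA"`.
#' @param chain_layout Named integer vector of residues per chain, e.g.
#'   `c(A = 10, B = 5)`.  Default: one chain `"A"` of `n_residues`.
#' @param charges,lj_sigma,lj_epsilon,pb_radius Per-atom parameters,
#'   recycled over atoms.
#' @param seed Integer seed fixing all downstream randomness.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 10, atoms_per_residue = 1,
                           chain_layout = NULL, charges = 0,
                           lj_sigma = 3.4, lj_epsilon = 0.1, pb_radius = 1.9,
                           seed = 1L) {
  if (is.null(chain_layout)) chain_layout <- stats::setNames(n_residues, "A")
  if (is.null(names(chain_layout)) || any(names(chain_layout) == "")) {
    abort("chain_layout must be a named vector of residue counts")
  }
  chain_layout <- vapply(chain_layout, as.integer, integer(1))
  if (any(chain_layout < 1)) abort("invalid spec: each chain needs at least 1 residue")
  if (sum(chain_layout) < 1) abort("invalid spec: zero residues")
  if (as.integer(atoms_per_residue) < 1) abort("invalid spec: atoms_per_residue must be >= 1")
  if (any(lj_sigma < 0) || any(lj_epsilon < 0) || any(pb_radius < 0)) {
    abort("invalid spec: sigma, epsilon and radius must be non-negative")
  }
  structure(list(chain_layout = chain_layout,
                 atoms_per_residue = as.integer(atoms_per_residue),
                 charges = charges, lj_sigma = lj_sigma,
                 lj_epsilon = lj_epsilon, pb_radius = pb_radius,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Build a toy molecular system from a specification
#'
#' Residues are laid out as extended chains (3.8 A C-alpha spacing along x,
#' chains stacked 30 A apart in z); extra atoms within a residue are offset
#' 1.5 A apart along y.  Parameters are recycled over atoms; total system
#' charge equals the sum of the recycled charges.
#'
#' @param spec A [synthetic_spec()].
#' @return A single-frame [md_trajectory] whose frame is the reference
#'   structure and whose topology carries the parameters.
#' @export
build_toy_system <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  apr <- spec$atoms_per_residue
  rows <- list()
  coords <- list()
  res_counter <- 0L
  for (ci in seq_along(spec$chain_layout)) {
    ch <- names(spec$chain_layout)[ci]
    for (r in seq_len(spec$chain_layout[ci])) {
      res_counter <- res_counter + 1L
      for (a in seq_len(apr)) {
        rows[[length(rows) + 1]] <- tibble(
          name = if (a == 1) "CA" else paste0("X", a - 1),
          element = "C",
          resid = r, resname = "GLY", chain = ch)
        coords[[length(coords) + 1]] <-
          c(3.8 * (r - 1), 1.5 * (a - 1), 30 * (ci - 1))
      }
    }
  }
  atoms <- bind_rows(rows)
  natom <- nrow(atoms)
  atoms$atom_id <- seq_len(natom)
  atoms$charge <- rep_len(spec$charges, natom)
  atoms$sigma <- rep_len(spec$lj_sigma, natom)
  atoms$epsilon <- rep_len(spec$lj_epsilon, natom)
  atoms$radius <- rep_len(spec$pb_radius, natom)
  xyz <- do.call(rbind, coords)
  md_trajectory(md_topology(atoms), xyz)
}

# residue table (one row per residue, in atom order) for a topology
residue_table <- function(top) {
  key <- paste(top$chain, top$resid)
  first <- !duplicated(key)
  tibble(chain = top$chain[first], resid = top$resid[first],
         resname = top$resname[first],
         res_index = seq_len(sum(first)))[order(which(first)), ]
}

# symmetric PSD factor via eigendecomposition; errors on negative spectrum
psd_factor <- function(sigma, tol = 1e-8) {
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-10))) {
    abort("covariance must be symmetric")
  }
  e <- eigen(sigma, symmetric = TRUE)
  scale <- max(abs(e$values), 1e-300)
  if (min(e$values) < -tol * scale) {
    abort(paste0("covariance is not positive semidefinite (min eigenvalue ",
                 format(min(e$values)), "); symmetric factorization failed"))
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Sample a trajectory with a prescribed inter-atom correlation structure
#'
#' Frames are the reference coordinates plus zero-mean Gaussian
#' displacements whose per-coordinate covariance across the selected atoms
#' is `covariance` (applied independently and identically to x, y and z, so
#' the displacement-vector cross-correlation of atoms i and j is exactly
#' the normalized covariance).  Atoms outside `selection` stay fixed.
#'
#' @param system A toy system from [build_toy_system()] (or any single-frame
#'   trajectory providing reference coordinates).
#' @param covariance Symmetric positive-semidefinite matrix over the
#'   selected atoms (Angstrom^2 per coordinate).
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed; the draw is bit-reproducible.
#' @param selection Atom indices covered by `covariance` (default: all).
#' @return List with `trajectory` (an [md_trajectory]) and `ground_truth`
#'   (list with `true_correlation`, `true_rmsf`, `selection`).
#' @export
sample_correlated_trajectory <- function(system, covariance, n_frames,
                                         seed = 1L, selection = NULL) {
  if (n_frames < 2) abort("n_frames must be >= 2")
  ref <- frame_coords(system, 1)
  N <- nrow(ref)
  sel <- if (is.null(selection)) seq_len(N) else check_selection(selection, N)
  covariance <- as.matrix(covariance)
  if (nrow(covariance) != length(sel)) {
    abort("covariance dimension must match the selection size")
  }
  L <- psd_factor(covariance)
  set.seed(as.integer(seed))
  coords <- array(rep(ref, n_frames), dim = c(N, 3, n_frames))
  for (d in 1:3) {
    Z <- matrix(rnorm(n_frames * length(sel)), n_frames, length(sel))
    D <- Z %*% L   # frames x atoms displacements for coordinate d
    coords[sel, d, ] <- coords[sel, d, ] + t(D)
  }
  sdv <- sqrt(diag(covariance))
  denom <- outer(sdv, sdv)
  truec <- covariance / ifelse(denom > 0, denom, NA_real_)
  diag(truec)[diag(covariance) > 0] <- 1
  list(trajectory = md_trajectory(system$topology, coords),
       ground_truth = list(true_correlation = truec,
                           true_rmsf = sqrt(3 * diag(covariance)),
                           selection = sel))
}

#' Sample two collective-variable series from a multi-basin mixture
#'
#' Each frame picks a basin with the prescribed occupancy probabilities and
#' draws (cv1, cv2) from an isotropic Gaussian at that basin's center.
#' Per-frame basin membership is recorded as ground truth.
#'
#' @param basin_centers Numeric `k x 2` matrix of (cv1, cv2) centers
#'   (Angstrom).
#' @param basin_widths Per-basin Gaussian s.d. (Angstrom), recycled.
#' @param occupancies Per-basin probabilities summing to 1 (within 1e-9).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return List with `series` (tibble: `frame`, `cv1`, `cv2`, `basin`) and
#'   `ground_truth` (list with `true_occupancies`, `basin`).
#' @export
sample_two_state_cv <- function(basin_centers, basin_widths, occupancies,
                                n_frames, seed = 1L) {
  basin_centers <- rbind(basin_centers)
  k <- nrow(basin_centers)
  if (ncol(basin_centers) != 2) abort("basin_centers must be k x 2")
  basin_widths <- rep_len(basin_widths, k)
  if (any(basin_widths <= 0)) abort("invalid spec: basin widths must be > 0")
  if (length(occupancies) != k) abort("one occupancy per basin is required")
  if (abs(sum(occupancies) - 1) > 1e-9) {
    abort("invalid spec: occupancies must sum to 1 (within 1e-9)")
  }
  set.seed(as.integer(seed))
  basin <- sample.int(k, n_frames, replace = TRUE, prob = occupancies)
  cv1 <- basin_centers[basin, 1] + rnorm(n_frames, 0, basin_widths[basin])
  cv2 <- basin_centers[basin, 2] + rnorm(n_frames, 0, basin_widths[basin])
  list(series = tibble(frame = seq_len(n_frames), cv1 = cv1, cv2 = cv2,
                       basin = basin),
       ground_truth = list(true_occupancies = occupancies, basin = basin))
}

# half-up rounding, so contact frame counts are deterministic at .5
round_half_up <- function(x) floor(x + 0.5)

#' Sample a trajectory with exact per-pair contact fractions
#'
#' Each listed residue pair sits at `contact_distance` in exactly
#' `round(fraction * n_frames)` frames (half-up rounding) and at
#' `apart_distance` otherwise; which frames are in contact is randomized by
#' the seed.  Pairs must not share residues (infeasible schedules error).
#' Residues not involved in any pair are parked far from everything.
#'
#' @param system Toy system from [build_toy_system()].
#' @param pair_fractions Data frame with columns `i`, `j` (residue indices
#'   into the system's residue order) and `fraction` in `[0, 1]`.
#' @param contact_distance,apart_distance Distances in Angstrom with
#'   `contact_distance < apart_distance`.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return List with `trajectory` and `ground_truth` (per-pair exact
#'   contact fractions `n_contact / n_frames`).
#' @export
sample_contact_schedule <- function(system, pair_fractions, contact_distance,
                                    apart_distance, n_frames, seed = 1L) {
  if (contact_distance >= apart_distance) {
    abort("contact_distance must be smaller than apart_distance")
  }
  pf <- as_tibble(pair_fractions)
  if (any(pf$fraction < 0 | pf$fraction > 1)) abort("fractions must lie in [0, 1]")
  involved <- c(pf$i, pf$j)
  if (anyDuplicated(involved)) {
    abort("infeasible schedule: a residue appears in more than one pair")
  }
  top <- system$topology
  rt <- residue_table(top)
  n_res <- nrow(rt)
  if (any(involved < 1 | involved > n_res)) abort("pair residue index out of range")

  set.seed(as.integer(seed))
  # base coordinates: each pair in its own region, spectators far away
  base <- matrix(0, nrow(top), 3)
  atom_res <- match(paste(top$chain, top$resid), paste(rt$chain, rt$resid))
  place_residue <- function(res, origin) {
    rows <- which(atom_res == res)
    for (k in seq_along(rows)) {
      base[rows[k], ] <<- origin + c(0, 1.5 * (k - 1), 0)
    }
  }
  spectators <- setdiff(seq_len(n_res), involved)
  for (s in seq_along(spectators)) {
    place_residue(spectators[s], c(50 * s, -1000, 0))
  }
  coords <- array(0, dim = c(nrow(top), 3, n_frames))
  truth <- pf
  truth$n_contact <- round_half_up(truth$fraction * n_frames)
  truth$exact_fraction <- truth$n_contact / n_frames
  for (f in seq_len(n_frames)) coords[, , f] <- base
  for (p in seq_len(nrow(pf))) {
    origin_i <- c(0, 1000 * p, 0)
    place_residue(pf$i[p], origin_i)
    rows_j <- which(atom_res == pf$j[p])
    rows_i <- which(atom_res == pf$i[p])
    contact_frames <- sample.int(n_frames, truth$n_contact[p])
    for (f in seq_len(n_frames)) {
      coords[rows_i, , f] <- base[rows_i, ]
      d <- if (f %in% contact_frames) contact_distance else apart_distance
      for (k in seq_along(rows_j)) {
        coords[rows_j[k], , f] <- origin_i + c(d, 1.5 * (k - 1), 0)
      }
    }
  }
  # spectators keep base coordinates in every frame (already set)
  list(trajectory = md_trajectory(top, coords),
       ground_truth = list(true_contact_fractions = truth))
}
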