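#' Least-squares rigid-body fit of one coordinate set onto another
#'
#' Kabsch algorithm: the optimal rotation (determinant +1, no reflection)
#' and translation minimising the RMSD between corresponding atoms.
#'
#' @param mobile,reference Numeric `n x 3` matrices with matched rows.
#' @return List with `rotation` (3x3), `translation_mobile` and
#'   `translation_ref` (centroids), and `rmsd` after fitting.
#' @export
kabsch_fit <- function(mobile, reference) {
  if (nrow(mobile) != nrow(reference)) abort("coordinate sets differ in size")
  if (nrow(mobile) < 3) abort("superposition is under-determined: fewer than 3 atoms")
  pbar <- colMeans(mobile); qbar <- colMeans(reference)
  P <- sweep(mobile, 2, pbar); Q <- sweep(reference, 2, qbar)
  sv <- svd(crossprod(P, Q))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)) {
    abort("degenerate geometry: selected atoms are (near-)collinear")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- P %*% R
  list(rotation = R, translation_mobile = pbar, translation_ref = qbar,
       rmsd = sqrt(mean(rowSums((aligned - Q)^2))))
}

apply_fit <- function(coords, fit) {
  sweep(sweep(coords, 2, fit$translation_mobile) %*% fit$rotation, 2,
        fit$translation_ref, `+`)
}

#' Superpose every frame of a trajectory on a reference
#'
#' Each frame receives its own optimal rotation/translation (fit on
#' `selection`, applied to all atoms).  The per-frame RMSD over the
#' selection after fitting is attached as attribute `"rmsd"` and available
#' through [frame_rmsd()].
#'
#' @param mobile An [md_trajectory].
#' @param reference Reference: a frame number of `mobile` (default 1, i.e.
#'   the initial structure) or an `N x 3` coordinate matrix.
#' @param selection Atom indices used for the fit (default: all atoms).
#' @return The aligned [md_trajectory].
#' @export
superpose <- function(mobile, reference = 1, selection = NULL) {
  N <- n_atoms(mobile)
  sel <- if (is.null(selection)) seq_len(N) else check_selection(selection, N)
  if (length(sel) < 3) abort("superposition is under-determined: fewer than 3 atoms selected")
  ref <- if (is.matrix(reference)) reference else frame_coords(mobile, reference)
  refsel <- ref[sel, , drop = FALSE]
  out <- mobile$coords
  rmsd <- numeric(n_frames(mobile))
  for (f in seq_len(n_frames(mobile))) {
    m <- frame_coords(mobile, f)
    fit <- kabsch_fit(m[sel, , drop = FALSE], refsel)
    out[, , f] <- apply_fit(m, fit)
    rmsd[f] <- fit$rmsd
  }
  res <- md_trajectory(mobile$topology, out, time = mobile$time)
  attr(res, "rmsd") <- tibble(frame = seq_along(rmsd), rmsd = rmsd)
  res
}

#' Per-frame RMSD recorded by [superpose()]
#' @param traj A trajectory returned by [superpose()].
#' @return Tibble with columns `frame`, `rmsd` (Angstrom).
#' @export
frame_rmsd <- function(traj) {
  r <- attr(traj, "rmsd")
  if (is.null(r)) abort("trajectory carries no RMSD record; run superpose() first")
  r
}

#' Root-mean-square fluctuation per atom
#'
#' RMSF_i = sqrt(< |r_i - <r_i>|^2 >) about the time-mean position of each
#' atom.  The trajectory is assumed already superposed; with `refit = TRUE`
#' a two-pass alignment to the mean structure is performed first (fit to
#' the running mean, recompute the mean, fit again).
#'
#' @param traj An aligned [md_trajectory] with at least 2 frames.
#' @param selection Atom indices (default all).
#' @param refit Align to the mean structure (2 passes) before measuring.
#' @return Tibble with `atom_id`, `resid`, `name`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection = NULL, refit = FALSE) {
  if (n_frames(traj) < 2) {
    abort("fluctuations are undefined for a single frame")
  }
  N <- n_atoms(traj)
  sel <- if (is.null(selection)) seq_len(N) else check_selection(selection, N)
  tr <- traj
  if (refit) {
    for (pass in 1:2) {
      mean_struct <- apply(tr$coords, c(1, 2), mean)
      tr <- superpose(tr, reference = mean_struct, selection = sel)
    }
  }
  cs <- tr$coords[sel, , , drop = FALSE]
  mu <- apply(cs, c(1, 2), mean)
  dev2 <- sweep(cs, c(1, 2), mu)^2
  msf <- apply(dev2, 1, mean) * 3  # mean over frames and xyz, times 3 dims
  top <- tr$topology[sel, ]
  tibble(atom_id = top$atom_id, resid = top$resid, name = top$name,
         rmsf = sqrt(msf))
}
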