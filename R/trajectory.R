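#' Build a trajectory object
#'
#' A trajectory binds an [md_topology] to an `N x 3 x F` array of Cartesian
#' coordinates in Angstrom (atoms x xyz x frames), with an optional per-frame
#' time stamp in nanoseconds.
#'
#' @param topology An [md_topology] with N atoms.
#' @param coords Numeric array `N x 3 x F`, or an `N x 3` matrix for a
#'   single-frame trajectory.
#' @param time Optional numeric vector of length F (ns).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, coords, time = NULL) {
  top <- as_topology(topology)
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  d <- dim(coords)
  if (length(d) != 3 || d[2] != 3) abort("coords must be an N x 3 x F array")
  if (d[1] != nrow(top)) {
    abort(paste0("coordinate atom count (", d[1], ") does not match topology (",
                 nrow(top), ")"))
  }
  if (d[3] < 1) abort("trajectory must contain at least one frame")
  if (!all(is.finite(coords))) abort("coordinates must all be finite")
  if (!is.null(time) && length(time) != d[3]) {
    abort("time stamps must have one value per frame")
  }
  structure(list(topology = top, coords = coords, time = time),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", n_frames(x), " frames x ", n_atoms(x), " atoms\n",
      sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An [md_trajectory].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Number of atoms in a trajectory
#' @param traj An [md_trajectory].
#' @return Integer atom count.
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an N x 3 coordinate matrix
#' @param traj An [md_trajectory].
#' @param frame 1-based frame number.
#' @return Numeric `N x 3` matrix.
#' @export
frame_coords <- function(traj, frame = 1) {
  f <- as.integer(frame)
  if (f < 1 || f > n_frames(traj)) abort("frame index out of range")
  m <- traj$coords[, , f, drop = FALSE]
  dim(m) <- dim(traj$coords)[1:2]
  m
}

#' Keep a subset of frames
#' @param traj An [md_trajectory].
#' @param frames Integer vector of 1-based frame numbers.
#' @return A new [md_trajectory].
#' @export
subset_frames <- function(traj, frames) {
  frames <- as.integer(frames)
  if (any(frames < 1 | frames > n_frames(traj))) abort("frame indices out of range")
  md_trajectory(traj$topology, traj$coords[, , frames, drop = FALSE],
                time = if (!is.null(traj$time)) traj$time[frames])
}

#' Coordinates as a tidy tibble
#'
#' @param x An [md_trajectory].
#' @param ... Unused.
#' @return A tibble with columns `frame`, `atom_id`, `x`, `y`, `z`.
#' @export
tidy.md_trajectory <- function(x, ...) {
  FF <- n_frames(x); N <- n_atoms(x)
  tibble(
    frame = rep(seq_len(FF), each = N),
    atom_id = rep(x$topology$atom_id, times = FF),
    x = as.vector(x$coords[, 1, ]),
    y = as.vector(x$coords[, 2, ]),
    z = as.vector(x$coords[, 3, ])
  )
}

#' @export
glance.md_trajectory <- function(x, ...) {
  tibble(n_frames = n_frames(x), n_atoms = n_atoms(x),
         n_residues = nrow(unique(x$topology[c("chain", "resid")])),
         n_chains = length(unique(x$topology$chain)))
}
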