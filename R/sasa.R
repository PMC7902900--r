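#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom accessible area by spherical quadrature: each atom's surface is
#' sampled on a deterministic generalized-spiral (golden-angle) point set at
#' radius `r_atom + probe_radius`; a point is accessible when outside every
#' occluder's probe-expanded sphere.  The point set uses no random numbers,
#' so results are exactly reproducible.
#'
#' @param x An [md_trajectory] (one frame is used) or an `N x 3` coordinate
#'   matrix (then `radii` must be given).
#' @param selection Atoms whose area is measured (default all).
#' @param occluders Atoms that occlude (default: the selection).
#' @param probe_radius Solvent probe radius, Angstrom (default 1.4).
#' @param n_points Quadrature points per atom (default 960).
#' @param frame Frame number when `x` is a trajectory.
#' @param radii Per-atom radii when `x` is a bare coordinate matrix.
#' @return Tibble of class `sasa_result` with `atom_id`, `resid`, `name`,
#'   `area` (Angstrom^2); total SASA as attribute `"total"`, plus
#'   `"probe_radius"` and `"n_points"`.
#' @export
shrake_rupley_sasa <- function(x, selection = NULL, occluders = NULL,
                               probe_radius = 1.4, n_points = 960,
                               frame = 1, radii = NULL) {
  if (inherits(x, "md_trajectory")) {
    coords <- frame_coords(x, frame)
    top <- x$topology
    radii <- top$radius
  } else {
    coords <- as.matrix(x)
    if (is.null(radii)) abort("radii are required with bare coordinates")
    top <- NULL
  }
  N <- nrow(coords)
  sel <- if (is.null(selection)) seq_len(N) else check_selection(selection, N)
  occ <- if (is.null(occluders)) sel else check_selection(occluders, N, "occluders")
  need <- union(sel, occ)
  bad <- need[!is.finite(radii[need]) | radii[need] <= 0]
  if (length(bad)) {
    id <- if (is.null(top)) bad[1] else top$atom_id[bad[1]]
    abort(paste0("missing or non-positive radius for atom ", id))
  }
  area <- sasa_kernel(coords, radii, as.integer(sel) - 1L,
                      as.integer(occ) - 1L, probe_radius, as.integer(n_points))
  out <- if (is.null(top)) {
    tibble(atom_id = sel, resid = NA_integer_, name = NA_character_, area = area)
  } else {
    tibble(atom_id = top$atom_id[sel], resid = top$resid[sel],
           name = top$name[sel], area = area)
  }
  attr(out, "total") <- sum(area)
  attr(out, "probe_radius") <- probe_radius
  attr(out, "n_points") <- as.integer(n_points)
  class(out) <- c("sasa_result", class(out))
  out
}

#' Total accessible area of a SASA result
#' @param x A `sasa_result`.
#' @return Total SASA in Angstrom^2.
#' @export
total_sasa <- function(x) attr(x, "total")
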