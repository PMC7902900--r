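#' Molecular-mechanics interaction energy between two atom groups
#'
#' Cross-group pairwise sums with no distance cutoff:
#' electrostatics `E_ele = 332.0636 * sum(q_i q_j / (eps * r_ij))` and
#' Lennard-Jones `E_vdW = sum 4 eps_ij ((sig_ij/r)^12 - (sig_ij/r)^6)` with
#' Lorentz-Berthelot combining (`sig_ij = (sig_i + sig_j)/2`,
#' `eps_ij = sqrt(eps_i eps_j)`).
#'
#' @param x An [md_trajectory] (with parameters on its topology) or an
#'   `N x 3` coordinate matrix plus a `parameters` data frame.
#' @param group_a,group_b Disjoint atom index vectors.
#' @param dielectric Relative dielectric constant (default 1).
#' @param frame Frame number when `x` is a trajectory.
#' @param parameters Data frame with `charge`, `sigma`, `epsilon` when `x`
#'   is a bare matrix.
#' @return Named list with `e_vdw` and `e_ele` (kcal/mol).
#' @export
mm_pair_energy <- function(x, group_a, group_b, dielectric = 1, frame = 1,
                           parameters = NULL) {
  if (inherits(x, "md_trajectory")) {
    coords <- frame_coords(x, frame)
    parameters <- x$topology
  } else {
    coords <- as.matrix(x)
    if (is.null(parameters)) abort("parameters are required with bare coordinates")
  }
  N <- nrow(coords)
  ga <- check_selection(group_a, N, "group_a")
  gb <- check_selection(group_b, N, "group_b")
  if (length(intersect(ga, gb))) abort("groups must be disjoint")
  need <- c(ga, gb)
  for (col in c("charge", "sigma", "epsilon")) {
    if (anyNA(parameters[[col]][need])) {
      abort(paste0("missing ", col, " for atom ",
                   need[which(is.na(parameters[[col]][need]))[1]]))
    }
  }
  A <- coords[ga, , drop = FALSE]; B <- coords[gb, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 1e-6)) {
    w <- which(r < 1e-6, arr.ind = TRUE)[1, ]
    abort(paste0("overlapping atoms: ", ga[w[1]], " and ", gb[w[2]],
                 " are closer than 1e-6 A"))
  }
  qa <- parameters$charge[ga]; qb <- parameters$charge[gb]
  e_ele <- COULOMB_KCAL * sum(outer(qa, qb) / r) / dielectric
  sij <- outer(parameters$sigma[ga], parameters$sigma[gb], `+`) / 2
  eij <- sqrt(outer(parameters$epsilon[ga], parameters$epsilon[gb]))
  sr6 <- (sij / r)^6
  e_vdw <- sum(4 * eij * (sr6^2 - sr6))
  list(e_vdw = e_vdw, e_ele = e_ele)
}

#' Poisson-Boltzmann grid specification
#'
#' @param spacing Grid spacing in Angstrom (> 0); default 0.5.
#' @param padding Padding beyond the solute extent on every side, Angstrom
#'   (>= 5); default 8.
#' @param eps_in Interior (solute) dielectric (default 1).
#' @param eps_out Exterior (solvent) dielectric (default 80).
#' @param ionic If `TRUE` include linearized Debye-Hueckel screening.
#' @param debye_length Debye length in Angstrom when `ionic`.
#' @param tol SOR convergence tolerance on the potential update
#'   (kcal/mol/e).
#' @param max_iter Iteration cap.
#' @return List of class `pb_grid_spec`.
#' @export
pb_grid_spec <- function(spacing = 0.5, padding = 8, eps_in = 1, eps_out = 80,
                         ionic = FALSE, debye_length = 8, tol = 1e-4,
                         max_iter = 20000L) {
  if (spacing <= 0) abort("grid spacing must be positive")
  if (padding < 5) abort("padding must be at least 5 Angstrom")
  if (eps_in < 1 || eps_out < eps_in) abort("require eps_out >= eps_in >= 1")
  structure(list(spacing = spacing, padding = padding, eps_in = eps_in,
                 eps_out = eps_out, ionic = ionic,
                 debye_length = debye_length, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "pb_grid_spec")
}

#' Polar solvation energy by finite-difference Poisson-Boltzmann
#'
#' Solves the (linearized) Poisson-Boltzmann equation on a uniform grid
#' twice — once with the exterior dielectric outside the union of atom
#' spheres, once with the interior dielectric everywhere — on the identical
#' grid with identical charge spreading, so the grid self-energy cancels in
#' the difference: `dE_PB = 1/2 sum_i q_i (phi_solv(i) - phi_ref(i))`.
#'
#' @param x An [md_trajectory] or `N x 3` coordinate matrix.
#' @param selection Solute atoms (default all).
#' @param grid A [pb_grid_spec()].
#' @param frame Frame number for trajectories.
#' @param parameters Data frame with `charge` and `radius` for bare
#'   coordinates.
#' @param box Optional explicit box: list with `origin` (length-3) and
#'   `lengths` (length-3, Angstrom).  Default: solute extent plus padding.
#' @param eval_all If `TRUE`, also return the reaction-field potential at
#'   every selected atom (used for per-residue decomposition).
#' @return Polar solvation energy in kcal/mol; with `eval_all`, a list
#'   with `energy` and per-atom `phi_rf`.
#' @export
solve_pb <- function(x, selection = NULL, grid = pb_grid_spec(), frame = 1,
                     parameters = NULL, box = NULL, eval_all = FALSE) {
  if (inherits(x, "md_trajectory")) {
    coords <- frame_coords(x, frame)
    parameters <- x$topology
  } else {
    coords <- as.matrix(x)
    if (is.null(parameters)) abort("parameters are required with bare coordinates")
  }
  N <- nrow(coords)
  sel <- if (is.null(selection)) seq_len(N) else check_selection(selection, N)
  q <- parameters$charge[sel]; radii <- parameters$radius[sel]
  if (anyNA(q)) abort("missing charge for a selected atom")
  if (anyNA(radii) || any(radii <= 0)) {
    abort(paste0("missing or non-positive PB radius for atom ",
                 sel[which(is.na(radii) | radii <= 0)[1]]))
  }
  cs <- coords[sel, , drop = FALSE]
  h <- grid$spacing
  if (is.null(box)) {
    lo <- apply(cs - radii, 2, min) - grid$padding
    hi <- apply(cs + radii, 2, max) + grid$padding
  } else {
    lo <- box$origin; hi <- box$origin + box$lengths
  }
  npts <- pmax(ceiling((hi - lo) / h) + 1L, 5L)
  if (any((cs - radii) < rep(lo + 2 * h, each = nrow(cs))) ||
      any((cs + radii) > rep(lo + (npts - 1) * h - 2 * h, each = nrow(cs)))) {
    abort("insufficient padding: solute touches the grid boundary")
  }
  kappa <- if (isTRUE(grid$ionic)) 1 / grid$debye_length else 0
  omega <- 2 / (1 + pi / max(npts))
  run <- function(uniform) {
    r <- pb_fd_solve(cs, q, radii, lo, as.integer(npts), h,
                     grid$eps_in, grid$eps_out, uniform, kappa, cs,
                     grid$tol, grid$max_iter, omega)
    if (!r$converged) {
      abort(paste0("PB solver did not converge within ", grid$max_iter,
                   " iterations (residual ", format(r$residual), ")"))
    }
    r$phi
  }
  phi_solv <- run(FALSE)
  phi_ref <- run(TRUE)
  phi_rf <- phi_solv - phi_ref
  energy <- 0.5 * sum(q * phi_rf)
  if (eval_all) list(energy = energy, phi_rf = phi_rf) else energy
}

#' Nonpolar solvation energy from total SASA
#'
#' Linear surface-area model `E_nonpolar = gamma * SASA + b` with the
#' standard surface-tension coefficient gamma = 0.00542 kcal/mol/A^2 and
#' offset b = 0.92 kcal/mol.
#'
#' @param total_sasa Total solvent-accessible surface area, Angstrom^2
#'   (>= 0).
#' @param gamma Surface tension coefficient (kcal/mol/A^2).
#' @param b Offset (kcal/mol).
#' @return Nonpolar solvation energy, kcal/mol.
#' @export
nonpolar_energy <- function(total_sasa, gamma = 0.00542, b = 0.92) {
  if (any(total_sasa < 0)) abort("SASA cannot be negative")
  gamma * total_sasa + b
}

#' MM/PBSA binding free energy over a trajectory
#'
#' Single-trajectory protocol: receptor and ligand conformations are cut
#' from the complex frames, so the internal-energy difference is
#' identically zero and the molecular-mechanics difference reduces to the
#' receptor-ligand cross terms.  Per frame,
#' `dG_binding = dE_MM + dG_solv` with `dE_MM = dE_vdW + dE_ele + dE_int`
#' and `dG_solv = dE_PB + dE_nonpolar`; the entropy term -TdS is omitted
#' (recorded as such in the report).  All three PB runs share the
#' complex's grid box so discretization noise partially cancels.
#'
#' @param traj An [md_trajectory] with charges, LJ parameters and radii.
#' @param receptor_sel,ligand_sel Disjoint atom selections jointly covering
#'   the complex.
#' @param grid A [pb_grid_spec()].
#' @param frame_stride Analyse every `frame_stride`-th frame (default 10).
#' @param dielectric MM electrostatic dielectric (default 1).
#' @param probe_radius,n_points SASA settings.
#' @param include_pb Set `FALSE` to skip the PB term (then `dE_PB = 0`).
#' @return Object of class `binding_report`: per-frame energy tibble,
#'   summary tibble (mean and sd per component), frame count, and
#'   selections.
#' @export
mmpbsa_binding <- function(traj, receptor_sel, ligand_sel,
                           grid = pb_grid_spec(), frame_stride = 10,
                           dielectric = 1, probe_radius = 1.4, n_points = 960,
                           include_pb = TRUE) {
  N <- n_atoms(traj)
  rec <- check_selection(receptor_sel, N, "receptor selection")
  lig <- check_selection(ligand_sel, N, "ligand selection")
  if (length(intersect(rec, lig))) abort("receptor and ligand selections overlap")
  cpx <- sort(c(rec, lig))
  frames <- seq(1, n_frames(traj), by = frame_stride)
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    mm <- mm_pair_energy(traj, rec, lig, dielectric = dielectric, frame = f)
    if (include_pb) {
      coords <- frame_coords(traj, f)
      rsel <- coords[cpx, , drop = FALSE]
      radii <- traj$topology$radius[cpx]
      h <- grid$spacing
      lo <- apply(rsel - radii, 2, min) - grid$padding
      hi <- apply(rsel + radii, 2, max) + grid$padding
      box <- list(origin = lo, lengths = hi - lo)
      e_pb <- solve_pb(traj, cpx, grid, frame = f, box = box) -
        solve_pb(traj, rec, grid, frame = f, box = box) -
        solve_pb(traj, lig, grid, frame = f, box = box)
    } else {
      e_pb <- 0
    }
    s_cpx <- total_sasa(shrake_rupley_sasa(traj, cpx, probe_radius = probe_radius,
                                           n_points = n_points, frame = f))
    s_rec <- total_sasa(shrake_rupley_sasa(traj, rec, probe_radius = probe_radius,
                                           n_points = n_points, frame = f))
    s_lig <- total_sasa(shrake_rupley_sasa(traj, lig, probe_radius = probe_radius,
                                           n_points = n_points, frame = f))
    e_np <- nonpolar_energy(s_cpx) - nonpolar_energy(s_rec) - nonpolar_energy(s_lig)
    e_int <- 0  # single-trajectory protocol: identical bound/unbound conformers
    e_mm <- mm$e_vdw + mm$e_ele + e_int
    g_solv <- e_pb + e_np
    rows[[fi]] <- tibble(frame = f, e_vdw = mm$e_vdw, e_ele = mm$e_ele,
                         e_int = e_int, e_pb = e_pb, e_nonpolar = e_np,
                         e_mm = e_mm, g_solv = g_solv,
                         g_binding = e_mm + g_solv)
  }
  per_frame <- bind_rows(rows)
  comp <- c("e_vdw", "e_ele", "e_int", "e_pb", "e_nonpolar", "e_mm",
            "g_solv", "g_binding")
  summary <- tibble(
    component = comp,
    mean = vapply(comp, function(k) mean(per_frame[[k]]), numeric(1),
                  USE.NAMES = FALSE),
    sd = vapply(comp, function(k) if (nrow(per_frame) > 1) sd(per_frame[[k]]) else 0,
                numeric(1), USE.NAMES = FALSE))
  structure(list(frames = per_frame, summary = summary,
                 n_frames = nrow(per_frame),
                 receptor = rec, ligand = lig,
                 entropy = "omitted (-TdS set to 0)"),
            class = "binding_report")
}

#' @export
print.binding_report <- function(x, ...) {
  cat("<binding_report> ", x$n_frames, " frame(s); entropy ", x$entropy, "\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.binding_report <- function(x, ...) x$summary

#' @export
glance.binding_report <- function(x, ...) {
  s <- x$summary
  tibble(dg_binding = s$mean[s$component == "g_binding"],
         dg_sd = s$sd[s$component == "g_binding"],
         de_mm = s$mean[s$component == "e_mm"],
         dg_solv = s$mean[s$component == "g_solv"],
         n_frames = x$n_frames)
}

#' Per-residue decomposition of the binding free energy
#'
#' Molecular-mechanics cross terms are attributed half to the residue of
#' each partner atom; the polar term per atom is
#' `1/2 q_i (phi_RF_complex(i) - phi_RF_own(i))`; the nonpolar term is
#' `gamma` times the per-atom SASA change, with the constant `-b` of the
#' linear model spread uniformly over residues so that residue sums
#' reproduce each total exactly.
#'
#' @inheritParams mmpbsa_binding
#' @return Tibble with one row per residue (`chain`, `resid`, `resname`,
#'   `side`) and mean contributions `e_vdw`, `e_ele`, `e_polar`,
#'   `e_nonpolar`, `total` (kcal/mol), averaged over analysed frames.
#'   Totals per component are attached as attribute `"totals"`.
#' @export
per_residue_decomposition <- function(traj, receptor_sel, ligand_sel,
                                      grid = pb_grid_spec(), frame_stride = 10,
                                      dielectric = 1, probe_radius = 1.4,
                                      n_points = 960, include_pb = TRUE) {
  N <- n_atoms(traj)
  rec <- check_selection(receptor_sel, N, "receptor selection")
  lig <- check_selection(ligand_sel, N, "ligand selection")
  if (length(intersect(rec, lig))) abort("receptor and ligand selections overlap")
  cpx <- sort(c(rec, lig))
  top <- traj$topology
  reskey <- paste(top$chain, top$resid)
  resof <- match(reskey, unique(reskey[cpx]))
  nres <- length(unique(reskey[cpx]))
  frames <- seq(1, n_frames(traj), by = frame_stride)

  acc <- matrix(0, nres, 4,
                dimnames = list(NULL, c("e_vdw", "e_ele", "e_polar", "e_nonpolar")))
  for (f in frames) {
    coords <- frame_coords(traj, f)
    A <- coords[rec, , drop = FALSE]; B <- coords[lig, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    r <- sqrt(pmax(d2, 0))
    if (any(r < 1e-6)) abort("overlapping atoms across the interface")
    qa <- top$charge[rec]; qb <- top$charge[lig]
    ele <- COULOMB_KCAL * outer(qa, qb) / r / dielectric
    sij <- outer(top$sigma[rec], top$sigma[lig], `+`) / 2
    eij <- sqrt(outer(top$epsilon[rec], top$epsilon[lig]))
    sr6 <- (sij / r)^6
    vdw <- 4 * eij * (sr6^2 - sr6)
    per_atom <- function(M) {  # half to each side's atom, summed by residue
      va <- rowSums(M) / 2; vb <- colSums(M) / 2
      out <- numeric(nres)
      out_add <- tapply(c(va, vb), resof[c(rec, lig)], sum)
      out[as.integer(names(out_add))] <- out_add
      out
    }
    acc[, "e_vdw"] <- acc[, "e_vdw"] + per_atom(vdw)
    acc[, "e_ele"] <- acc[, "e_ele"] + per_atom(ele)

    if (include_pb) {
      radii <- top$radius[cpx]
      h <- grid$spacing
      lo <- apply(coords[cpx, , drop = FALSE] - radii, 2, min) - grid$padding
      hi <- apply(coords[cpx, , drop = FALSE] + radii, 2, max) + grid$padding
      box <- list(origin = lo, lengths = hi - lo)
      pc <- solve_pb(traj, cpx, grid, frame = f, box = box, eval_all = TRUE)
      pr <- solve_pb(traj, rec, grid, frame = f, box = box, eval_all = TRUE)
      pl <- solve_pb(traj, lig, grid, frame = f, box = box, eval_all = TRUE)
      phi_own <- numeric(length(cpx))
      phi_own[match(rec, cpx)] <- pr$phi_rf
      phi_own[match(lig, cpx)] <- pl$phi_rf
      atom_pol <- 0.5 * top$charge[cpx] * (pc$phi_rf - phi_own)
      pol <- numeric(nres)
      pol_add <- tapply(atom_pol, resof[cpx], sum)
      pol[as.integer(names(pol_add))] <- pol_add
      acc[, "e_polar"] <- acc[, "e_polar"] + pol
    }

    sa_c <- shrake_rupley_sasa(traj, cpx, probe_radius = probe_radius,
                               n_points = n_points, frame = f)
    sa_r <- shrake_rupley_sasa(traj, rec, probe_radius = probe_radius,
                               n_points = n_points, frame = f)
    sa_l <- shrake_rupley_sasa(traj, lig, probe_radius = probe_radius,
                               n_points = n_points, frame = f)
    own <- numeric(length(cpx))
    own[match(rec, cpx)] <- sa_r$area
    own[match(lig, cpx)] <- sa_l$area
    atom_np <- 0.00542 * (sa_c$area - own)
    np <- numeric(nres)
    np_add <- tapply(atom_np, resof[cpx], sum)
    np[as.integer(names(np_add))] <- np_add
    acc[, "e_nonpolar"] <- acc[, "e_nonpolar"] + np - 0.92 / nres
  }
  acc <- acc / length(frames)
  resrows <- cpx[!duplicated(resof[cpx])]
  out <- tibble(chain = top$chain[resrows], resid = top$resid[resrows],
                resname = top$resname[resrows],
                side = ifelse(resrows %in% rec, "receptor", "ligand"),
                e_vdw = acc[, "e_vdw"], e_ele = acc[, "e_ele"],
                e_polar = acc[, "e_polar"], e_nonpolar = acc[, "e_nonpolar"])
  out$total <- out$e_vdw + out$e_ele + out$e_polar + out$e_nonpolar
  attr(out, "totals") <- colSums(acc)
  class(out) <- c("residue_decomposition", class(out))
  out
}
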