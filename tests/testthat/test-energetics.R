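test_that("pairwise MM terms match closed forms", {
  top <- md_topology(tibble::tibble(
    name = "CA", element = "C", resid = 1:2, resname = "GLY", chain = "A",
    charge = c(1, -1), sigma = 3.4, epsilon = 0.1, radius = 1.9))
  r <- 3.320636
  traj <- md_trajectory(top, rbind(c(0, 0, 0), c(r, 0, 0)))
  e <- mm_pair_energy(traj, 1, 2)
  expect_equal(e$e_ele, -100, tolerance = 1e-10)

  # LJ node at r = sigma, minimum -eps at r = 2^(1/6) sigma
  at_sigma <- md_trajectory(top, rbind(c(0, 0, 0), c(3.4, 0, 0)))
  expect_equal(mm_pair_energy(at_sigma, 1, 2)$e_vdw, 0, tolerance = 1e-12)
  rmin <- 2^(1 / 6) * 3.4
  at_min <- md_trajectory(top, rbind(c(0, 0, 0), c(rmin, 0, 0)))
  expect_equal(mm_pair_energy(at_min, 1, 2)$e_vdw, -0.1, tolerance = 1e-10)

  # dielectric scaling and error paths
  expect_equal(mm_pair_energy(traj, 1, 2, dielectric = 4)$e_ele, -25,
               tolerance = 1e-10)
  overlap <- md_trajectory(top, rbind(c(0, 0, 0), c(0, 0, 1e-9)))
  expect_error(mm_pair_energy(overlap, 1, 2), "overlapping")
  expect_error(mm_pair_energy(traj, 1, 1), "disjoint")
})

test_that("nonpolar model reproduces its two constants", {
  expect_identical(nonpolar_energy(0), 0.92)
  expect_equal(nonpolar_energy(1000), 6.34, tolerance = 1e-12)
  expect_identical(nonpolar_energy(500, gamma = 0), 0.92)
  expect_error(nonpolar_energy(-1), "negative")
})

test_that("PB solver reproduces the Born ion and null limits", {
  top <- md_topology(tibble::tibble(
    name = "CA", element = "C", resid = 1, resname = "ION", chain = "A",
    charge = 1, sigma = 3.4, epsilon = 0.1, radius = 2))
  ion <- md_trajectory(top, rbind(c(0, 0, 0)))
  born <- -(332.0636 / (2 * 2)) * (1 - 1 / 80)
  e <- solve_pb(ion, grid = pb_grid_spec(spacing = 0.5, padding = 8))
  expect_equal(e, born, tolerance = 0.05 * abs(born))

  # no charge, and no dielectric contrast, both give zero
  top0 <- top; top0$charge <- 0
  ion0 <- md_trajectory(top0, rbind(c(0, 0, 0)))
  expect_equal(solve_pb(ion0, grid = pb_grid_spec(spacing = 1)), 0)
  same_eps <- pb_grid_spec(spacing = 0.5, eps_in = 1, eps_out = 1)
  expect_lt(abs(solve_pb(ion, grid = same_eps)), 1e-6)

  expect_error(pb_grid_spec(padding = 2), "at least 5")
  expect_error(pb_grid_spec(spacing = 0), "positive")
})

test_that("PB energy is invariant under solute translation", {
  top <- md_topology(tibble::tibble(
    name = "CA", element = "C", resid = 1:2, resname = "GLY", chain = "A",
    charge = c(0.5, -0.5), sigma = 3.4, epsilon = 0.1, radius = 1.9))
  a <- md_trajectory(top, rbind(c(0, 0, 0), c(3, 0.5, 0.25)))
  b <- md_trajectory(top, rbind(c(11, -7, 3), c(14, -6.5, 3.25)))
  g <- pb_grid_spec(spacing = 0.5, padding = 6)
  expect_equal(solve_pb(a, grid = g), solve_pb(b, grid = g), tolerance = 1e-6)
})

test_that("binding assembly satisfies its exact identities and a brute-force frame", {
  traj <- toy_complex(nres_rec = 2, nres_lig = 1, gap = 5)
  g <- pb_grid_spec(spacing = 0.6, padding = 6)
  rep <- mmpbsa_binding(traj, receptor_sel = 1:2, ligand_sel = 3, grid = g,
                        frame_stride = 1)
  pf <- rep$frames
  # single-trajectory protocol
  expect_identical(pf$e_int, 0)
  expect_equal(pf$g_binding, pf$e_mm + pf$g_solv, tolerance = 1e-10)
  expect_equal(pf$e_mm, pf$e_vdw + pf$e_ele + pf$e_int, tolerance = 1e-12)
  expect_equal(pf$g_solv, pf$e_pb + pf$e_nonpolar, tolerance = 1e-12)
  expect_match(rep$entropy, "omitted")

  # independent hand assembly of every component for the single frame
  mm <- mm_pair_energy(traj, 1:2, 3)
  expect_equal(pf$e_vdw, mm$e_vdw, tolerance = 1e-12)
  expect_equal(pf$e_ele, mm$e_ele, tolerance = 1e-12)
  coords <- frame_coords(traj, 1)
  radii <- traj$topology$radius
  lo <- apply(coords - radii, 2, min) - g$padding
  hi <- apply(coords + radii, 2, max) + g$padding
  box <- list(origin = lo, lengths = hi - lo)
  e_pb_ref <- solve_pb(traj, 1:3, g, box = box) -
    solve_pb(traj, 1:2, g, box = box) - solve_pb(traj, 3, g, box = box)
  expect_equal(pf$e_pb, e_pb_ref, tolerance = 1e-6)
  s_ref <- total_sasa(shrake_rupley_sasa(traj, 1:3)) -
    total_sasa(shrake_rupley_sasa(traj, 1:2)) -
    total_sasa(shrake_rupley_sasa(traj, 3))
  expect_equal(pf$e_nonpolar, 0.00542 * s_ref - 0.92, tolerance = 1e-9)

  # swapping receptor and ligand labels leaves the binding energy unchanged
  rep2 <- mmpbsa_binding(traj, receptor_sel = 3, ligand_sel = 1:2, grid = g,
                         frame_stride = 1)
  expect_equal(rep$frames$g_binding, rep2$frames$g_binding, tolerance = 1e-9)

  expect_error(mmpbsa_binding(traj, 1:2, 2:3, grid = g), "overlap")
})

test_that("MM terms vanish when the ligand is moved far away", {
  near <- toy_complex(nres_rec = 2, nres_lig = 1, gap = 5)
  far <- toy_complex(nres_rec = 2, nres_lig = 1, gap = 60)
  e <- mm_pair_energy(far, 1:2, 3)
  expect_lt(abs(e$e_vdw), 1e-3)
  # net-neutral receptor: monopole falls off, but allow the looser bound
  expect_lt(abs(e$e_ele) , 1e-1)
  enear <- mm_pair_energy(near, 1:2, 3)
  expect_gt(abs(enear$e_vdw) + abs(enear$e_ele), abs(e$e_vdw) + abs(e$e_ele))
})

test_that("per-residue decomposition conserves every component total", {
  traj <- toy_complex(nres_rec = 2, nres_lig = 1, gap = 5,
                      charges = c(0.8, 0, -0.8))
  g <- pb_grid_spec(spacing = 0.6, padding = 6)
  dec <- per_residue_decomposition(traj, 1:2, 3, grid = g, frame_stride = 1)
  rep <- mmpbsa_binding(traj, 1:2, 3, grid = g, frame_stride = 1)
  tot <- attr(dec, "totals")
  expect_equal(sum(dec$e_vdw), rep$frames$e_vdw, tolerance = 1e-6)
  expect_equal(sum(dec$e_ele), rep$frames$e_ele, tolerance = 1e-6)
  expect_equal(sum(dec$e_polar), rep$frames$e_pb, tolerance = 1e-6)
  expect_equal(sum(dec$e_nonpolar), rep$frames$e_nonpolar, tolerance = 1e-6)
  expect_equal(sum(dec$total),
               rep$frames$g_binding, tolerance = 1e-6)

  # the neutral receptor residue carries no electrostatic cross term
  expect_equal(dec$e_ele[dec$resid == 2 & dec$side == "receptor"],
               0.5 * mm_pair_energy(traj, 2, 3)$e_ele, tolerance = 1e-12)
  expect_equal(dec$e_ele[dec$resid == 2 & dec$side == "receptor"], 0,
               tolerance = 1e-12)

  # a single-residue ligand's row equals the full ligand-side interaction
  lig_row <- dec[dec$side == "ligand", ]
  expect_equal(lig_row$e_vdw, rep$frames$e_vdw / 2, tolerance = 1e-9)
})
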