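geom_fixture <- function() {
  top <- md_topology(tibble::tibble(
    name = "CA", element = "C", resid = 1:4, resname = "GLY", chain = "A",
    charge = 0, sigma = 3.4, epsilon = 0.1, radius = 1.9))
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0), c(1, 0, 0), c(0, 1, 0))
  md_trajectory(top, xyz)
}

test_that("distances and angles match closed forms and flag degeneracies", {
  traj <- geom_fixture()
  gs <- geometry_series(traj, distances = rbind(c(1, 2)),
                        angles = rbind(c(3, 1, 4)))
  expect_equal(gs$value[gs$type == "distance"], 5)
  expect_equal(gs$value[gs$type == "angle"], 90)

  # coincident atoms make the angle undefined in that frame, flagged
  bad <- traj
  bad$coords[3, , 1] <- bad$coords[1, , 1]
  expect_warning(
    gs2 <- geometry_series(bad, angles = rbind(c(3, 1, 4))),
    "undefined")
  expect_true(is.na(gs2$value[1]))
  expect_false(gs2$defined[1])

  expect_error(geometry_series(traj, distances = rbind(c(1, 99))), "out of range")
})

test_that("CV histograms place their modes at the generator's basin centers", {
  out <- sample_two_state_cv(rbind(c(4, 6), c(9, 11)), 0.25, c(0.7, 0.3),
                             n_frames = 20000, seed = 8)
  h <- geometry_histogram(
    tibble::tibble(label = "d1", value = out$series$cv1), bin_width = 0.1)
  # two local modes, near 4 and 9
  m1 <- h$mid[which.max(h$density * (h$mid < 6.5))]
  m2 <- h$mid[which.max(h$density * (h$mid > 6.5))]
  expect_lt(abs(m1 - 4), 0.2)
  expect_lt(abs(m2 - 9), 0.2)
  # densities integrate to 1
  expect_equal(sum(h$density) * 0.1, 1, tolerance = 1e-6)
})

test_that("contact persistence is an exact rational count with inclusive cutoff", {
  sys <- build_toy_system(synthetic_spec(n_residues = 4))
  sched <- sample_contact_schedule(
    sys, tibble::tibble(i = 1, j = 3, fraction = 0.6),
    contact_distance = 4.5, apart_distance = 8, n_frames = 10, seed = 4)
  # distance exactly equal to the cutoff counts as contact
  pt <- persistence_table(sched$trajectory, rbind(c(1, 3)), cutoff = 4.5)
  expect_identical(pt$fraction, 0.6)
  # an infinitesimally smaller cutoff drops all contact frames
  pt2 <- persistence_table(sched$trajectory, rbind(c(1, 3)), cutoff = 4.5 - 1e-9)
  expect_identical(pt2$fraction, 0)
  # permanently bridged pair
  always <- sample_contact_schedule(
    sys, tibble::tibble(i = 1, j = 3, fraction = 1),
    contact_distance = 3, apart_distance = 8, n_frames = 10, seed = 4)
  expect_identical(
    persistence_table(always$trajectory, rbind(c(1, 3)), cutoff = 4)$fraction, 1)
})

test_that("salt-bridge mode uses charged-group atoms and validates residue types", {
  top <- md_topology(tibble::tibble(
    name = c("CA", "OD1", "OD2", "CA", "NZ", "CA"),
    element = c("C", "O", "O", "C", "N", "C"),
    resid = c(1, 1, 1, 2, 2, 3),
    resname = c("ASP", "ASP", "ASP", "LYS", "LYS", "GLY"),
    chain = "A"))
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
               c(10, 0, 0), c(4.5, 0, 0), c(20, 0, 0))
  traj <- md_trajectory(top, xyz)
  pt <- persistence_table(traj, tibble::tibble(i = 1, j = 2), cutoff = 4.0,
                          mode = "salt-bridge")
  # min over charged groups: OD1 (1,0,0) to NZ (4.5,0,0) = 3.5 <= 4
  expect_identical(pt$fraction, 1)
  d <- attr(pt, "distances")$distance
  expect_equal(d, 3.5)
  expect_error(
    persistence_table(traj, tibble::tibble(i = 1, j = 3), cutoff = 4,
                      mode = "salt-bridge"), "not basic")
})

test_that("Welch t statistic matches the textbook case and stats::t.test", {
  w <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(w$parameter, 4.0, tolerance = 1e-10)

  # identical samples: t = 0 (guard the zero-variance branch with jitter)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)

  # anti-symmetry and agreement with the established implementation
  set.seed(10)
  a <- rnorm(40, 1); b <- rnorm(25, 1.4, 2)
  w1 <- welch_t(a, b); w2 <- welch_t(b, a)
  expect_equal(w1$statistic, -w2$statistic)
  ref <- stats::t.test(a, b)
  expect_equal(w1$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w1$parameter, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w1$p.value, ref$p.value, tolerance = 1e-12)

  expect_error(welch_t(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Shrake-Rupley SASA matches sphere analytics and buried/additive limits", {
  # isolated sphere: 4 pi (1.9 + 1.4)^2
  s <- shrake_rupley_sasa(rbind(c(0, 0, 0)), radii = 1.9)
  expect_equal(total_sasa(s), 4 * pi * 3.3^2, tolerance = 0.01)

  # two atoms 50 A apart: additivity of isolated values
  s2 <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(50, 0, 0)), radii = c(1.9, 1.9))
  expect_equal(total_sasa(s2), 2 * total_sasa(s), tolerance = 1e-10)

  # an atom enclosed by a tight shell of neighbours is fully buried
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1),
                cbind(c(1, 1, 1, 1, -1, -1, -1, -1) / sqrt(3),
                      c(1, 1, -1, -1, 1, 1, -1, -1) / sqrt(3),
                      c(1, -1, 1, -1, 1, -1, 1, -1) / sqrt(3)))
  shell <- rbind(c(0, 0, 0), 2.5 * dirs)
  s3 <- shrake_rupley_sasa(shell, radii = rep(1.9, nrow(shell)))
  expect_equal(s3$area[1], 0)

  expect_error(shrake_rupley_sasa(rbind(c(0, 0, 0)), radii = NA_real_),
               "radius for atom 1")
})
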