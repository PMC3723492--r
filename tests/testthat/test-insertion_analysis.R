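bilayer_system <- function(head_offset = 12, center_z = 24, box_z = 48) {
  bil <- build_bilayer(head_offset = head_offset, center_z = center_z,
                       box_z = box_z, jitter = 0)
  lip <- seq_len(n_atoms(bil))
  pho <- which(bil$atoms$name == "HD")
  list(s = bil, lip = lip, pho = pho)
}

test_that("membrane frame is symmetric, equivariant, and leaflet-accurate", {
  b <- bilayer_system(center_z = 24)
  mf <- membrane_frame(b$s, b$lip, b$pho)
  expect_equal(mf$center_z, 24, tolerance = 1e-9)
  expect_equal(mf$phosphate_z_upper, 36, tolerance = 1e-9)
  expect_equal(mf$phosphate_z_lower, 12, tolerance = 1e-9)
  s2 <- b$s; s2$xyz[, 3] <- s2$xyz[, 3] + 5
  mf2 <- membrane_frame(s2, b$lip, b$pho)
  expect_equal(mf2$center_z, 29, tolerance = 1e-9)
  flat <- b$s; flat$xyz[, 3] <- 24
  expect_error(membrane_frame(flat, b$lip, b$pho), "not separable")
})

test_that("insertion angle recovers constructed tilts within 1 degree", {
  b <- bilayer_system()
  mf <- membrane_frame(b$s, b$lip, b$pho)
  helix <- build_helix(paste(rep("A", 36), collapse = ""))
  ca <- select_atoms(helix, "name CA")
  for (tau in c(0, 15, 30, 45, 60, 75, 90)) {
    th <- tau * pi / 180
    # helix built along z: rotate about y so the axis makes angle tau
    # with the x-y plane
    R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
                3, 3, byrow = TRUE)
    s <- helix
    s$xyz <- helix$xyz %*% R  # axis (0,0,1) -> (sin(th), 0, cos(th))...
    ang <- insertion_angle(s, ca, mf)
    expect_lt(abs(ang - (90 - tau)), 1)
  }
  one <- helix; one$xyz[] <- 1
  expect_error(insertion_angle(one, ca, mf), "degenerate")
})

test_that("depth is the unsigned CA-com distance from the bilayer center", {
  b <- bilayer_system(center_z = 24)
  mf <- membrane_frame(b$s, b$lip, b$pho)
  atoms <- data.frame(name = "CA", element = "C", res_name = "ALA",
                      res_id = 1:4, chain = "A", mass = c(12, 12, 24, 12),
                      charge = 0, is_bead = FALSE)
  s <- structure3d(atoms, cbind(0, 0, c(24, 24, 24, 24)))
  expect_equal(insertion_depth(s, 1:4, mf), 0)
  s$xyz[, 3] <- c(40, 44, 42, 46)
  # mass-weighted mean computed independently
  want <- abs(sum(c(40, 44, 42, 46) * c(12, 12, 24, 12)) / 60 - 24)
  expect_equal(insertion_depth(s, 1:4, mf), want, tolerance = 1e-12)
  expect_error(insertion_depth(s, integer(0), mf), "empty")
})

test_that("depth and angle are invariant under translation and rotation about z", {
  b <- bilayer_system()
  helix <- build_helix(anchor_sequence())
  sys <- combine_structures(helix, b$s, box = b$s$box)
  lip <- which(sys$atoms$res_name == "TOY")
  pho <- which(sys$atoms$name == "HD")
  ca <- select_atoms(sys, "name CA")
  mf <- membrane_frame(sys, lip, pho)
  a0 <- insertion_angle(sys, ca, mf)
  d0 <- insertion_depth(sys, ca, mf)
  th <- 1.1
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  s2 <- sys
  s2$xyz <- sweep(sys$xyz %*% t(Rz), 2, c(7, -3, 9), "+")
  mf2 <- membrane_frame(s2, lip, pho)
  expect_equal(insertion_angle(s2, ca, mf2), a0, tolerance = 1e-9)
  expect_equal(insertion_depth(s2, ca, mf2), d0, tolerance = 1e-9)
})

test_that("depth tables use population sd and carry classes", {
  b <- bilayer_system(center_z = 0, box_z = 60)
  helix <- build_helix("WSK", resid_start = 1L)
  sys <- combine_structures(helix, b$s, box = b$s$box)
  lip <- which(sys$atoms$res_name == "TOY")
  pho <- which(sys$atoms$name == "HD")
  mf <- membrane_frame(sys, lip, pho)
  x1 <- sys$xyz; x1[seq_len(n_atoms(helix)), 3] <- 15
  x2 <- sys$xyz; x2[seq_len(n_atoms(helix)), 3] <- 17
  traj <- trajectory(sys, list(x1, x2), times = c(0, 1))
  dt <- residue_depth_table(traj, 1:3, mf)
  expect_equal(dt$mean_depth, rep(16, 3))
  expect_equal(dt$sd_depth, rep(1, 3))  # population convention
  expect_identical(dt$class, c("hydrophobic", "polar", "basic"))
  static <- trajectory(sys, list(x1, x1), times = c(0, 1))
  expect_equal(residue_depth_table(static, 1:3, mf)$sd_depth, rep(0, 3))
})

test_that("group summaries reproduce the reference class means", {
  ref <- anchor_depth_reference()
  gs <- group_depth_summary(ref)
  expect_lt(abs(gs$mean_depth[gs$class == "hydrophobic"] - 16.0), 0.1)
  expect_lt(abs(gs$mean_depth[gs$class == "basic"] - 18.6), 0.1)
  expect_lt(abs(gs$mean_depth[gs$class == "polar"] - 19.3), 0.1)
  single <- data.frame(class = "basic", mean_depth = 18.3, sd_depth = 1.6)
  expect_equal(group_depth_summary(single)$mean_depth, 18.3)
})

test_that("hydrogen bonds follow the geometric criterion", {
  # ideal linear N-H...O at 2.9 A donor-acceptor
  xyz <- rbind(c(0, 0, 0),      # N (donor)
               c(1, 0, 0),      # H
               c(2.9, 0, 0),    # O (acceptor)
               c(0, 4.0, 0))    # O too far
  s <- structure3d(data.frame(name = c("N", "H", "O", "O2"),
                              element = c("N", "H", "O", "O"),
                              res_id = c(1, 1, 2, 3)), xyz)
  donors <- cbind(1L, 2L)
  expect_identical(hbond_count(s, donors, 3L), 1L)
  expect_identical(hbond_count(s, donors, 4L), 0L)
  # bent geometry below 150 degrees fails
  bent <- s; bent$xyz[3, ] <- c(1, 2.4, 0)
  expect_identical(hbond_count(bent, donors, 3L), 0L)
  expect_error(hbond_count(s, 1L, 3L), "heavy_only")
  expect_identical(hbond_count(s, 1L, 3L, heavy_only = TRUE), 1L)
})

test_that("hydrogen-bond counts match the brute triple loop", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 14
    xyz <- matrix(runif(3 * n, 0, 8), n, 3)
    s <- structure3d(data.frame(name = "X", element = "O",
                                res_id = seq_len(n)), xyz)
    donors <- cbind(1:4, 5:8)
    acceptors <- 9:14
    expect_identical(hbond_count(s, donors, acceptors),
                     brute_hbond(s, donors, acceptors))
  }
})

test_that("RMSD and RMSF behave on constructed trajectories", {
  helix <- build_helix("ACDEFG")
  x <- helix$xyz
  traj_same <- trajectory(helix, list(x, x, x))
  expect_equal(rmsd_series(traj_same), rep(0, 3), tolerance = 1e-10)
  expect_equal(max(rmsf_profile(traj_same)), 0, tolerance = 1e-10)
  # rotated frame with fit on: zero RMSD
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  traj_rot <- trajectory(helix, list(x, x %*% t(R)))
  expect_lt(rmsd_series(traj_rot)[2], 1e-8)
  expect_gt(rmsd_series(traj_rot, fit = FALSE)[2], 1)
  # two-frame toy against hand-computed displacement
  x2 <- x; x2[1, ] <- x2[1, ] + c(3, 0, 0)
  traj2 <- trajectory(helix, list(x, x2))
  want <- sqrt(9 / n_atoms(helix))
  expect_equal(rmsd_series(traj2, fit = FALSE)[2], want, tolerance = 1e-10)
})

test_that("density profiles are normalized and peak at construction offsets", {
  b <- bilayer_system(head_offset = 12, center_z = 24)
  traj <- trajectory(b$s, list(b$s$xyz))
  mf <- membrane_frame(b$s, b$lip, b$pho)
  groups <- list(heads = b$pho,
                 tails = which(b$s$atoms$name %in% c("TL1", "TL2")))
  prof <- density_profile(traj, groups, mf, bin_width = 1)
  sums <- rowSums(prof$density) * 1
  expect_equal(unname(sums), c(1, 1), tolerance = 1e-12)
  peaks <- prof$mids[prof$density["heads", ] > 0]
  expect_true(all(abs(abs(peaks) - 12) < 1.01))
  expect_warning(density_profile(traj, list(none = integer(0)), mf), "empty")
  # all mass at one z: single occupied bin
  one <- b$s; one$xyz[, 3] <- 30.2
  prof1 <- density_profile(trajectory(one, list(one$xyz)),
                           list(all = seq_len(n_atoms(one))), mf)
  expect_identical(sum(prof1$density > 0), 1L)
})

test_that("implicit-probe map equals the closed form for one atom / one frame", {
  atom <- structure3d(data.frame(name = "C", element = "C", res_id = 1,
                                 mass = 12),
                      matrix(c(10, 10, 10), 1, 3),
                      box = c(20, 20, 20))
  traj <- trajectory(atom, list(atom$xyz))
  g <- ils_map(traj, probe_epsilon = 1.2, probe_sigma = 3.7, spacing = 4,
               temperature = 300)
  vox <- as.matrix(expand.grid(x = g$x, y = g$y, z = g$z))
  r <- sqrt(rowSums(sweep(vox, 2, c(10, 10, 10))^2))
  want <- ifelse(r < 12 & r > 0, lj_shifted(pmax(r, 1e-9), 1.2, 3.7)$energy, 0)
  expect_equal(as.numeric(g$F), want, tolerance = 1e-9)
  # empty system: zero free energy everywhere
  empty <- structure3d(data.frame(name = character(0),
                                  element = character(0),
                                  res_id = integer(0)),
                       matrix(0, 0, 3), box = c(20, 20, 20))
  g0 <- ils_map(trajectory(empty, list(empty$xyz)), spacing = 5)
  expect_true(all(g0$F == 0))
  expect_error(ils_map(traj, spacing = 0.05), "resource guard")
})

test_that("implicit-probe map is invariant under frame reordering", {
  atom <- structure3d(data.frame(name = "C", element = "C", res_id = 1,
                                 mass = 12),
                      matrix(c(10, 10, 10), 1, 3), box = c(20, 20, 20))
  f1 <- atom$xyz; f2 <- atom$xyz + 1.5
  t12 <- trajectory(atom, list(f1, f2))
  t21 <- trajectory(atom, list(f2, f1))
  expect_equal(ils_map(t12, spacing = 5)$F, ils_map(t21, spacing = 5)$F,
               tolerance = 1e-12)
})
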