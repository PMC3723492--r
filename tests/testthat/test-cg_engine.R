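pair_cg <- function(r, classes = c("P", "P"), charges = c(0, 0),
                    box = 30) {
  beads <- structure3d(
    data.frame(name = "B", element = "X", res_name = "TST", res_id = 1:2,
               chain = "A", mass = 72, charge = charges, is_bead = TRUE),
    rbind(c(5, 5, 5), c(5 + r, 5, 5)), box = c(box, box, box))
  cg_model(beads, classes)
}

test_that("shifted LJ vanishes smoothly at the 12 A cutoff", {
  ff <- default_forcefield()
  out <- lj_shifted(12.5, 4, 4.7)
  expect_identical(out$energy, 0)
  expect_identical(out$force, 0)
  near <- lj_shifted(11.9999, 4, 4.7)
  expect_lt(abs(near$energy), 1e-6)
  expect_lt(abs(near$force), 1e-6)
  expect_error(lj_shifted(-1, 4, 4.7), "r must be > 0")
})

test_that("LJ force is the exact derivative of the energy", {
  set.seed(7)
  r <- runif(200, 2.5, 13)
  h <- 1e-6
  f <- lj_shifted(r, 3.5, 4.7)$force
  dE <- (lj_shifted(r + h, 3.5, 4.7)$energy -
           lj_shifted(r - h, 3.5, 4.7)$energy) / (2 * h)
  expect_equal(f, -dE, tolerance = 1e-5)
})

test_that("shifted Coulomb matches an independent quadrature oracle", {
  # E(r) must equal the integral of the force from r to the cutoff
  rs <- c(3, 6, 9, 11)
  for (r0 in rs) {
    grid <- seq(r0, 12, length.out = 20001)
    f <- coulomb_shifted(grid, 1, 1)$force
    e_int <- sum((f[-1] + f[-length(f)]) / 2 * diff(grid))
    expect_equal(coulomb_shifted(r0, 1, 1)$energy, e_int, tolerance = 1e-6)
  }
  expect_identical(coulomb_shifted(6, 0, 1)$energy, 0)
  expect_identical(coulomb_shifted(12.5, 1, 1)$energy, 0)
  expect_identical(coulomb_shifted(12.5, 1, 1)$force, 0)
  expect_error(coulomb_shifted(0, 1, 1), "r must be > 0")
})

test_that("compute_forces agrees with the R brute-force oracle", {
  ff <- default_forcefield()
  for (seed in 1:12) {
    cg <- random_cg_instance(10, 26, seed, charged = seed %% 2 == 0)
    st <- sim_state(cg$beads$xyz, cg$beads$box[1:3])
    got <- compute_forces(st, cg, ff)
    want <- brute_nonbonded(st$coords, st$box, cg$classes,
                            cg$beads$atoms$charge, ff)
    expect_equal(got$energy, want$energy, tolerance = 1e-9)
    expect_equal(got$forces, want$forces, tolerance = 1e-8)
  }
})

test_that("neighbor-list and all-pairs evaluation are identical", {
  s <- random_box(12, 80, 40, seed = 11)
  cg <- fixture_cg(s)
  st <- sim_state(cg$beads$xyz, s$box[1:3])
  a <- compute_forces(st, cg)
  b <- compute_forces(st, cg, brute = TRUE)
  expect_equal(a$forces, b$forces, tolerance = 1e-12)
  expect_equal(a$energy, b$energy, tolerance = 1e-12)
})

test_that("trivial force cases behave", {
  ff <- default_forcefield()
  far <- compute_forces(sim_state(rbind(c(1, 1, 1), c(14, 1, 1)),
                                  c(30, 30, 30)), pair_cg(13), ff)
  expect_equal(far$energy, 0)
  expect_equal(max(abs(far$forces)), 0)
  # bonded pair at its reference length: zero bond force
  cg <- pair_cg(4.7)
  cg$bonds <- data.frame(i = 1L, j = 2L, r0 = 4.7, k = 25)
  out <- compute_forces(sim_state(cg$beads$xyz, c(30, 30, 30)), cg, ff)
  expect_equal(out$components[["bond"]], 0)
  expect_lt(max(abs(out$forces)), 1e-10)
  expect_error(compute_forces(sim_state(cg$beads$xyz, c(20, 30, 30)), cg, ff),
               "configuration error")
})

test_that("forces sum to zero for dense random systems", {
  for (seed in 1:4) {
    cg <- random_cg_instance(40, 27, seed, charged = TRUE)
    st <- sim_state(cg$beads$xyz, cg$beads$box[1:3])
    f <- compute_forces(st, cg)$forces
    expect_lt(max(abs(colSums(f))), 1e-8 * max(1, max(abs(f))))
  }
})

test_that("steepest descent finds the shifted-LJ pair minimum", {
  ff <- default_forcefield()
  sig <- 4.7
  cg <- pair_cg(1.2 * sig, classes = c("C", "C"))
  st <- steepest_descent(sim_state(cg$beads$xyz, c(30, 30, 30)), cg, ff,
                         max_steps = 2000, initial_step = 0.05)
  r_min <- sqrt(sum((st$coords[1, ] - st$coords[2, ])^2))
  # golden-section oracle on the 1-D shifted potential
  gs <- optimize(function(r) lj_shifted(r, ff$epsilon["C", "C"], sig)$energy,
                 c(3, 9), tol = 1e-10)
  expect_lt(abs(r_min - gs$minimum) / gs$minimum, 0.01)
})

test_that("minimization is monotone and stops at a minimum", {
  s <- random_box(8, 40, 30, seed = 5)
  cg <- fixture_cg(s)
  st0 <- sim_state(cg$beads$xyz, s$box[1:3])
  st <- steepest_descent(st0, cg, max_steps = 800, force_cap = 1e3)
  tr <- attr(st, "trace")
  expect_true(all(diff(tr) <= 1e-9))
  # restarting never increases the energy
  st2 <- steepest_descent(st, cg, max_steps = 50)
  expect_lte(attr(st2, "energy"), attr(st, "energy") + 1e-8)
})

test_that("MD runs are bitwise reproducible for the same seed", {
  s <- random_box(6, 40, 30, seed = 2)
  cg <- fixture_cg(s)
  st <- steepest_descent(sim_state(cg$beads$xyz, s$box[1:3]), cg,
                         max_steps = 300, force_cap = 1e3)
  st$velocities <- init_velocities(cg, 323, seed = 9)
  cfg <- integrator_config(seed = 31L)
  r1 <- run_md(st, cg, config = cfg, n_steps = 400, stride = 50)
  r2 <- run_md(st, cg, config = cfg, n_steps = 400, stride = 50)
  expect_identical(r1$state$coords, r2$state$coords)
  expect_identical(r1$state$velocities, r2$state$velocities)
  r3 <- run_md(st, cg, config = integrator_config(seed = 32L),
               n_steps = 400, stride = 50)
  expect_false(identical(r3$state$coords, r1$state$coords))
})

test_that("momentum is conserved with the thermostat off", {
  s <- nve_fixture()
  cg <- fixture_cg(s)
  st <- steepest_descent(sim_state(cg$beads$xyz, s$box[1:3]), cg,
                         max_steps = 500, force_cap = 1e3)
  st$velocities <- init_velocities(cg, 323, seed = 3)
  run <- run_md(st, cg, config = integrator_config(thermostat = FALSE,
                                                   seed = 4),
                n_steps = 3000, stride = 300)
  m <- cg$beads$atoms$mass
  p0 <- colSums(st$velocities * m)
  p1 <- colSums(run$state$velocities * m)
  expect_lt(max(abs(p1 - p0)), 1e-12)
})

test_that("the barostat leaves a configuration at the reference pressure alone", {
  # single force-free bead whose kinetic pressure equals p_ref exactly:
  # P_aa = m v_a^2 * KE_UNIT / V * PRESSURE_UNIT
  cst <- mem_constants()
  box <- c(30, 30, 30)
  m <- 72
  v1 <- sqrt(1 * prod(box) / (cst$PRESSURE_UNIT * m * cst$KE_UNIT))
  beads <- structure3d(
    data.frame(name = "B", element = "X", res_name = "TST", res_id = 1,
               chain = "A", mass = m, charge = 0, is_bead = TRUE),
    matrix(15, 1, 3), box = c(box, 90, 90, 90))
  # two beads far apart so nf > 0; both moving so each axis has p = p_ref
  beads2 <- structure3d(rbind(beads$atoms, beads$atoms), rbind(c(5, 5, 5),
                        c(20, 20, 20)), box = c(box, 90, 90, 90))
  beads2$atoms$res_id <- 1:2
  cg <- cg_model(beads2, c("C", "C"))
  ffz <- default_forcefield()
  ffz$epsilon[] <- 0  # force-free
  v_axis <- v1 / sqrt(2)  # two beads share the kinetic pressure
  st <- sim_state(beads2$xyz, box,
                  velocities = matrix(c(v_axis, -v_axis), 2, 3))
  cfg <- integrator_config(thermostat = FALSE, barostat = "berendsen",
                           seed = 1L)
  run <- run_md(st, cg, ffz, config = cfg, n_steps = 5, stride = 1)
  expect_equal(run$state$box, box, tolerance = 1e-12)
})

test_that("the barostat responds to off-reference pressure", {
  s <- random_box(10, 120, 32, seed = 6)
  cg <- fixture_cg(s)
  st <- steepest_descent(sim_state(cg$beads$xyz, s$box[1:3]), cg,
                         max_steps = 400, force_cap = 1e3)
  st$velocities <- init_velocities(cg, 323, seed = 7)
  run <- run_md(st, cg, config = integrator_config(barostat = "berendsen",
                                                   seed = 8),
                n_steps = 2000, stride = 200)
  expect_false(isTRUE(all.equal(run$state$box, st$box)))
  expect_true(all(run$state$box > 24))
})

test_that("anchoring detector labels touch-and-leave vs insertion", {
  bil <- build_bilayer(nx = 4, ny = 4, box_z = 60)
  prot <- build_helix("LLVV", resid_start = 1L)
  prot$xyz <- sweep(prot$xyz, 2, c(13, 13, 55) - colMeans(prot$xyz), "+")
  sys <- combine_structures(prot, bil, box = bil$box)
  cg <- fixture_cg(sys)
  top <- cg$beads
  base <- top$xyz
  pidx <- which(top$atoms$res_name != "TOY")
  lift <- function(dz) { x <- base; x[pidx, 3] <- x[pidx, 3] + dz; x }
  # frames: far, touch, far, inserted (dwell 3 frames), still inserted
  zs <- c(0, -20, 0, -24, -24.5, -24, -24.2)
  frames <- lapply(zs, lift)
  traj <- trajectory(top, frames, times = (seq_along(zs) - 1) * 1000)
  anchor <- which(top$atoms$name == "SC1")
  res <- detect_anchoring(traj, cg, anchor, contact_cutoff = 7, dwell = 3)
  expect_identical(res$n_collisions, 2L)
  expect_identical(res$events$productive, c(FALSE, TRUE))
  expect_equal(res$anchoring_time, 3000)
  # brute per-frame contact scan agrees with the event extent
  lipid <- which(top$atoms$res_name == "TOY")
  contact <- vapply(seq_along(frames), function(k) {
    d <- Inf
    for (i in pidx) d <- min(d, sqrt(min(rowSums(sweep(frames[[k]][lipid, ],
                                                       2, frames[[k]][i, ])^2))))
    d <= 7
  }, logical(1))
  runs <- rle(contact)
  expect_identical(res$n_collisions, sum(runs$values))
  # a protein that never approaches produces no events
  far <- trajectory(top, list(base, base), times = c(0, 1000))
  res2 <- detect_anchoring(far, cg, anchor)
  expect_identical(res2$n_collisions, 0L)
  expect_true(is.na(res2$anchoring_time))
})
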