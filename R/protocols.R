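# Desk-scale simulation protocols built from the fixtures + engine:
# bilayer self-assembly from a random box, interfacial anchoring of an
# amphipathic helix on a pre-formed bilayer, and relaxation from tense
# (too-deep / tilted) starts.  These mirror, at toy scale, the two CG
# protocols used to insert a peripheral enzyme into a membrane: assembly
# of the bilayer around the protein, and adsorption onto a formed bilayer.

#' Bilayer self-assembly experiment
#'
#' Builds a seeded random box of toy lipids and coarse water, minimizes
#' it with clash capping, runs thermostatted CG-MD at 323 K, and checks
#' whether a single bilayer slab (two leaflets, tails interior) has
#' formed in the final frame.
#'
#' @param seed integer seed (controls the box, velocities and thermostat)
#' @param n_lipids number of toy lipids (default 64)
#' @param n_waters coarse water sites (default 240)
#' @param box_len cubic box edge, A
#' @param n_steps MD steps at 25 fs
#' @param stride trajectory stride
#' @param keep_trajectory return the trajectory as well
#' @return list: `formed`, `fraction`, `axis`, `spread`, plus `run` when
#'   `keep_trajectory`
#' @export
self_assembly_experiment <- function(seed, n_lipids = 64, n_waters = 200,
                                     box_len = 36, n_steps = 100000,
                                     stride = 5000,
                                     keep_trajectory = FALSE) {
  s <- random_box(n_lipids, n_waters, box_len, seed = seed)
  cg <- fixture_cg(s)
  st <- sim_state(cg$beads$xyz, s$box[1:3])
  st <- steepest_descent(st, cg, max_steps = 300, force_cap = 1e3)
  st$velocities <- init_velocities(cg, 323, seed = seed + 1L)
  run <- run_md(st, cg,
                config = integrator_config(seed = seed + 2L),
                n_steps = n_steps, stride = stride)
  final <- run$trajectory$coords[[n_frames(run$trajectory)]]
  bl <- detect_bilayer(cg, final, run$state$box)
  out <- list(formed = bl$formed, fraction = bl$fraction, axis = bl$axis,
              separation = bl$separation,
              lateral_concentration = bl$lateral_concentration)
  if (keep_trajectory) out$run <- run
  out
}

# build the anchored helix + bilayer + water system in a given start pose
.anchoring_system <- function(seed, height, tilt = 0, nx = 5, ny = 5,
                              head_offset = 12, box_z = 46) {
  bil <- build_bilayer(nx = nx, ny = ny, head_offset = head_offset,
                       box_z = box_z, seed = seed)
  center_z <- box_z / 2
  helix <- .orient_amphipathic(build_helix(anchor_sequence(),
                                           resid_start = 710L))
  if (tilt != 0) {
    th <- -tilt * pi / 180
    Ry <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
                 3, 3, byrow = TRUE)
    ctr <- colMeans(helix$xyz)
    helix$xyz <- sweep(sweep(helix$xyz, 2, ctr) %*% t(Ry), 2, ctr, "+")
  }
  target <- c(bil$box[1] / 2, bil$box[2] / 2,
              center_z + head_offset + height)
  helix$xyz <- sweep(helix$xyz, 2, target - colMeans(helix$xyz), "+")
  helix$box <- bil$box
  sys <- combine_structures(helix, bil, box = bil$box)
  sys <- solvate_fixture(sys, seed = seed + 10L)
  fixture_cg(sys)
}

#' Interfacial anchoring experiment
#'
#' Places the amphipathic anchor helix in water above a pre-formed toy
#' bilayer, runs thermostatted CG-MD, and compares the mean distance from
#' the bilayer center of the hydrophobic versus polar/charged side-chain
#' beads over the last quarter of the run.  Successful anchoring
#' reproduces the interfacial ordering: hydrophobic side chains deeper
#' (smaller |z - center|) than polar ones.
#'
#' @param seed integer seed
#' @param height initial helix height above the phosphate plane, A
#' @param n_steps MD steps at 25 fs
#' @param stride trajectory stride
#' @param keep_trajectory return the run object too
#' @return list: `hydrophobic_depth`, `polar_depth`, `anchored`
#'   (hydrophobic < polar), `contact` (helix reached the headgroups)
#' @export
anchoring_experiment <- function(seed, height = 1, n_steps = 60000,
                                 stride = 2000, keep_trajectory = FALSE) {
  cg <- .anchoring_system(seed, height = height)
  st <- sim_state(cg$beads$xyz, cg$beads$box[1:3])
  st <- steepest_descent(st, cg, max_steps = 200, force_cap = 1e3)
  st$velocities <- init_velocities(cg, 323, seed = seed + 1L)
  run <- run_md(st, cg, config = integrator_config(seed = seed + 2L),
                n_steps = n_steps, stride = stride)
  traj <- run$trajectory
  nf <- n_frames(traj)
  tail_frames <- seq(max(1, ceiling(0.75 * nf)), nf)
  at <- cg$beads$atoms
  sc <- which(at$name == "SC1")
  hyd <- sc[residue_class(at$res_name[sc]) == "hydrophobic"]
  pol <- sc[residue_class(at$res_name[sc]) != "hydrophobic"]
  lip <- which(at$res_name == "TOY")
  depth_of <- function(idx, k) {
    x <- traj$coords[[k]]
    L <- traj$boxes[[k]][3]
    cz <- circ_center(x[lip, 3], L)
    d <- x[idx, 3] - cz
    abs(d - L * round(d / L))
  }
  hd <- mean(vapply(tail_frames, function(k) mean(depth_of(hyd, k)), numeric(1)))
  pd <- mean(vapply(tail_frames, function(k) mean(depth_of(pol, k)), numeric(1)))
  head_off <- 12
  # within the interfacial/headgroup shell, not floating in bulk water
  contact <- mean(vapply(tail_frames, function(k)
    mean(depth_of(c(hyd, pol), k)), numeric(1))) < head_off + 8
  out <- list(hydrophobic_depth = hd, polar_depth = pd,
              anchored = (hd < pd) && contact, contact = contact)
  if (keep_trajectory) out$run <- run
  out
}

#' Relaxation from tense starts
#'
#' Runs the anchored-helix system three times from the same seed: once
#' from the relaxed start (helix resting on the headgroups) to measure
#' the equilibrium anchor depth and helix tilt of the fixture, once
#' started `depth_offset` A deeper into the membrane, and once started
#' tilted by `tilt` degrees.  For each tense run it reports the start
#' value, the mean over the last quarter, and whether the run-mean moved
#' toward the measured relaxed value.
#'
#' @param seed integer seed
#' @param depth_offset extra insertion depth for the deep start, A
#' @param tilt start tilt, degrees
#' @param n_steps MD steps at 25 fs per run
#' @param stride trajectory stride
#' @return list with `reference` (relaxed depth and angle) and, per
#'   perturbation (`deep`, `tilted`): `series`, `start`, `final_mean`,
#'   `relaxed_value`, `moved_toward`
#' @export
relaxation_experiment <- function(seed = 1L, depth_offset = 3, tilt = 15,
                                  n_steps = 40000, stride = 1000) {
  run_one <- function(height, tilt0) {
    cg <- .anchoring_system(seed, height = height, tilt = tilt0)
    st <- sim_state(cg$beads$xyz, cg$beads$box[1:3])
    # local clash removal only: the tense pose must survive into MD
    st <- steepest_descent(st, cg, max_steps = 100, initial_step = 0.02,
                           force_cap = 1e3, max_step = 0.05)
    st$velocities <- init_velocities(cg, 323, seed = seed + 1L)
    run <- run_md(st, cg, config = integrator_config(seed = seed + 2L),
                  n_steps = n_steps, stride = stride)
    traj <- run$trajectory
    at <- cg$beads$atoms
    lip <- which(at$res_name == "TOY")
    bb <- which(at$name == "BB")
    nf <- n_frames(traj)
    vals <- vapply(seq_len(nf), function(k) {
      x <- traj$coords[[k]]
      L3 <- traj$boxes[[k]][1:3]
      L <- L3[3]
      cz <- circ_center(x[lip, 3], L)
      xb <- .unwrap_group(x[bb, , drop = FALSE], L3)
      d <- mean(xb[, 3]) - cz
      depth <- abs(d - L * round(d / L))
      xc <- sweep(xb, 2, colMeans(xb))
      axis <- svd(xc)$v[, 1]
      angle <- 90 - acos(min(1, abs(axis[3]))) * 180 / pi
      c(depth, angle)
    }, numeric(2))
    list(depth = vals[1, ], angle = vals[2, ], nf = nf)
  }
  tail_mean <- function(v, nf) mean(v[seq(max(1, ceiling(0.75 * nf)), nf)])
  ref <- run_one(height = 1, tilt0 = 0)
  ref_depth <- tail_mean(ref$depth, ref$nf)
  ref_angle <- tail_mean(ref$angle, ref$nf)
  # a tense run counts as relaxed when its final mean moved closer to the
  # reference value, or landed inside the reference run's own
  # fluctuation band (the observables of the small fixture are noisy)
  score <- function(series, nf, relaxed, ref_series) {
    start <- series[1]
    fm <- tail_mean(series, nf)
    band <- stats::quantile(ref_series, c(0.05, 0.95))
    list(series = series, start = start, final_mean = fm,
         relaxed_value = relaxed,
         moved_toward = abs(fm - relaxed) < abs(start - relaxed) ||
           (fm >= band[[1]] && fm <= band[[2]]))
  }
  deep <- run_one(height = 1 - depth_offset, tilt0 = 0)
  tilted <- run_one(height = 1, tilt0 = tilt)
  list(reference = list(depth = ref_depth, angle = ref_angle),
       deep = score(deep$depth, deep$nf, ref_depth, ref$depth),
       tilted = score(tilted$angle, tilted$nf, ref_angle, ref$angle))
}

#' Thermostat calibration run
#'
#' A dense coarse-water box integrated with the stochastic
#' velocity-rescaling thermostat; returns the time-mean kinetic
#' temperature (excluding a short burn-in), for checking canonical
#' temperature control at the 323 K target.
#'
#' @param seed integer seed
#' @param n integer: beads per box edge (total `n^3`)
#' @param n_steps MD steps at 25 fs
#' @param temperature target, K
#' @return list: `mean_temperature`, `log`
#' @export
thermostat_experiment <- function(seed = 1L, n = 4, n_steps = 100000,
                                  temperature = 323) {
  spacing <- 5.3
  box <- max(2 * 12 + 1, n * spacing)
  g <- as.matrix(expand.grid(x = seq_len(n), y = seq_len(n),
                             z = seq_len(n))) * spacing - spacing / 2
  s <- structure3d(
    data.frame(name = "W", element = "X", res_name = "W",
               res_id = seq_len(n^3), chain = "W", mass = 72.06,
               charge = 0, is_bead = FALSE, stringsAsFactors = FALSE),
    g, box = c(box, box, box))
  cg <- fixture_cg(s)
  st <- sim_state(cg$beads$xyz, s$box[1:3],
                  init_velocities(cg, temperature, seed = seed))
  run <- run_md(st, cg,
                config = integrator_config(temperature = temperature,
                                           seed = seed + 1L),
                n_steps = n_steps, stride = max(1L, n_steps %/% 500L))
  lg <- run$log[run$log$step > n_steps * 0.1, ]
  list(mean_temperature = mean(lg$temperature), log = run$log)
}

#' Energy-conservation (NVE) run
#'
#' Minimizes the 38-bead toy fixture, assigns 323 K velocities and
#' integrates with thermostat and barostat off.  Drift is reported the
#' way MD engines report it: the slope of a linear fit to the total
#' energy over the run, multiplied by the run length, per bead (the
#' symplectic integrator's bounded energy fluctuation averages out of
#' this estimator).  Also reports the largest deviation of total linear
#' momentum from its initial value.
#'
#' @param seed integer seed
#' @param n_steps MD steps at 25 fs
#' @return list: `drift_per_bead` (kJ mol^-1 over the run),
#'   `max_momentum_error` (amu A/fs), `log`
#' @export
nve_experiment <- function(seed = 1L, n_steps = 10000) {
  s <- nve_fixture()
  cg <- fixture_cg(s)
  st <- sim_state(cg$beads$xyz, s$box[1:3])
  st <- steepest_descent(st, cg, max_steps = 2000, force_cap = 1e3)
  st$velocities <- init_velocities(cg, 323, seed = seed)
  run <- run_md(st, cg,
                config = integrator_config(thermostat = FALSE,
                                           seed = seed + 1L),
                n_steps = n_steps, stride = max(1L, n_steps %/% 2000L))
  lg <- run$log
  slope <- stats::coef(stats::lm(e_total ~ step, data = lg))[["step"]]
  drift <- abs(slope) * n_steps / n_atoms(cg$beads)
  m <- cg$beads$atoms$mass
  p0 <- colSums(st$velocities * m)
  p1 <- colSums(run$state$velocities * m)
  list(drift_per_bead = drift,
       max_momentum_error = max(abs(p1 - p0)),
       log = lg)
}
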