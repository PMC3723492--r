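# cg_engine: R-facing surface of the coarse-grained MD engine.  The inner
# loops (neighbor lists, pair forces, leapfrog, thermostat, barostat,
# minimizer) live in src/engine.cpp; this file assembles systems, checks
# contracts and converts results into package containers.

#' Integrator configuration
#'
#' Defaults follow the simulation protocol the package emulates: 25 fs
#' timestep, 323 K stochastic velocity-rescaling thermostat, Berendsen
#' anisotropic pressure coupling at 1 bar with a 10 ps coupling constant
#' and compressibility 3e-5 bar^-1.
#'
#' @param dt timestep, fs
#' @param temperature thermostat target, K
#' @param thermostat_tau thermostat coupling time, fs
#' @param thermostat logical; couple the velocity-rescaling thermostat
#' @param barostat `"off"` or `"berendsen"`
#' @param p_ref reference pressure, bar
#' @param barostat_tau pressure coupling constant, ps
#' @param compressibility isothermal compressibility, bar^-1
#' @param anisotropic scale each box axis independently (default); when
#'   `FALSE` scaling is isotropic
#' @param semi_isotropic couple x and y together (membrane convention)
#' @param seed integer seed controlling every stochastic element of a run
#' @return list of class `integrator_config`
#' @export
integrator_config <- function(dt = 25, temperature = 323,
                              thermostat_tau = 1000, thermostat = TRUE,
                              barostat = c("off", "berendsen"),
                              p_ref = 1, barostat_tau = 10,
                              compressibility = 3e-5,
                              anisotropic = TRUE, semi_isotropic = FALSE,
                              seed = 1L) {
  barostat <- match.arg(barostat)
  if (dt <= 0) stop("dt must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  if (barostat_tau <= 0) stop("barostat_tau must be > 0")
  structure(list(dt = dt, temperature = temperature,
                 thermostat_tau = thermostat_tau, thermostat = thermostat,
                 barostat = barostat, p_ref = p_ref,
                 barostat_tau = barostat_tau,
                 compressibility = compressibility,
                 anisotropic = anisotropic,
                 semi_isotropic = semi_isotropic,
                 seed = as.integer(seed)),
            class = "integrator_config")
}

#' Simulation state
#'
#' @param coords `n x 3` coordinates, A
#' @param box orthorhombic box lengths (length 3), A
#' @param velocities `n x 3` velocities, A/fs; zero if omitted
#' @param time elapsed simulated time, fs
#' @return list of class `sim_state`
#' @export
sim_state <- function(coords, box, velocities = NULL, time = 0) {
  coords <- as.matrix(coords)
  if (is.null(velocities)) velocities <- matrix(0, nrow(coords), 3)
  if (!all(is.finite(coords)) || !all(is.finite(velocities)))
    stop("state arrays must be finite")
  box <- .check_box(box)[1:3]
  structure(list(coords = coords, velocities = as.matrix(velocities),
                 box = box, time = time),
            class = "sim_state")
}

#' Maxwell-Boltzmann velocities
#'
#' Draw velocities at a target temperature with the center-of-mass motion
#' removed, so runs with the thermostat off conserve total momentum.
#'
#' @param cg a [cg_model()]
#' @param temperature K
#' @param seed integer seed
#' @return `n x 3` velocity matrix, A/fs
#' @export
init_velocities <- function(cg, temperature, seed = 1L) {
  set.seed(seed)
  m <- cg$beads$atoms$mass
  n <- length(m)
  sd <- sqrt(.kB * temperature / (m * .KE_UNIT))
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  # remove center-of-mass drift
  p <- colSums(v * m)
  sweep(v, 2, p / sum(m))
}

# marshal a cg_model + forcefield into the argument set of the C++ kernels
.engine_args <- function(cg, ff) {
  cls <- match(cg$classes, ff$classes)
  if (anyNA(cls)) stop("bead class missing from force field: ",
                       paste(unique(cg$classes[is.na(cls)]), collapse = ", "))
  allb <- rbind(cg$bonds, cg$elastic)
  list(mass = cg$beads$atoms$mass,
       charge = cg$beads$atoms$charge,
       cls = as.integer(cls - 1L),
       eps = unname(ff$epsilon), sig = unname(ff$sigma),
       eps_r = ff$eps_r,
       lj_r1 = ff$lj_window[1], coul_r1 = ff$coul_window[1],
       rc = max(ff$lj_window[2], ff$coul_window[2]),
       bonds = matrix(as.integer(c(allb$i - 1L, allb$j - 1L)),
                      ncol = 2),
       bond_r0 = as.numeric(allb$r0), bond_k = as.numeric(allb$k),
       angles = matrix(as.integer(c(cg$angles$i - 1L, cg$angles$j - 1L,
                                    cg$angles$k_ - 1L)), ncol = 3),
       theta0 = cg$angles$theta0 * pi / 180,
       angle_k = as.numeric(cg$angles$k_angle))
}

#' Total energy, forces and virial of a configuration
#'
#' Sum of bond, angle, elastic-network, shifted LJ and shifted Coulomb
#' terms under minimum-image periodic boundaries.  With `brute = TRUE`
#' the nonbonded sum runs over all pairs with no neighbor list (useful as
#' an oracle; identical result).
#'
#' @param state a [sim_state()] (or bare `n x 3` matrix, with `box` taken
#'   from the model's beads)
#' @param cg a [cg_model()]
#' @param ff a [read_forcefield()] force field
#' @param brute skip the neighbor list and evaluate all pairs
#' @return list with `energy` (kJ mol^-1), `components` (bond, angle, lj,
#'   coulomb), `forces` (`n x 3`, kJ mol^-1 A^-1) and `virial` (per-axis)
#' @export
compute_forces <- function(state, cg, ff = default_forcefield(),
                           brute = FALSE) {
  if (!inherits(state, "sim_state")) {
    box <- if (!is.null(cg$beads$box)) cg$beads$box[1:3] else
      stop("no box available; provide a sim_state")
    state <- sim_state(as.matrix(state), box)
  }
  a <- .engine_args(cg, ff)
  if (any(state$box < 2 * a$rc))
    stop("configuration error: box smaller than twice the cutoff (",
         2 * a$rc, " A)")
  cpp_compute_forces(state$coords, state$box, a$mass, a$charge, a$cls,
                     a$eps, a$sig, a$eps_r, a$lj_r1, a$coul_r1, a$rc,
                     a$bonds, a$bond_r0, a$bond_k, a$angles, a$theta0,
                     a$angle_k, brute)
}

#' Steepest-descent energy minimization
#'
#' Adaptive-step steepest descent (step grows 1.2x on accepted moves,
#' shrinks 5x on rejected ones) with monotone non-increasing energy over
#' accepted steps.  Forces are capped component-wise during the search so
#' that random boxes with overlapping beads have a finite initial
#' gradient ("clash capping").
#'
#' @inheritParams compute_forces
#' @param max_steps maximum iterations (default 5000)
#' @param initial_step initial displacement of the largest force
#'   component, A
#' @param force_cap component-wise force cap, kJ mol^-1 A^-1 (0 disables)
#' @param tol stop when the largest force component falls below this
#' @param max_step ceiling on the adaptive step size, A (`Inf` by
#'   default; a small ceiling confines the minimizer to local clash
#'   removal and prevents large collective motions)
#' @return the minimized [sim_state()], with attributes `energy`, `steps`
#'   and `trace` (energy after each accepted/rejected iteration)
#' @export
steepest_descent <- function(state, cg, ff = default_forcefield(),
                             max_steps = 5000, initial_step = 0.2,
                             force_cap = 1e4, tol = 1e-4,
                             max_step = Inf) {
  a <- .engine_args(cg, ff)
  res <- cpp_minimize(state$coords, state$box, a$mass, a$charge, a$cls,
                      a$eps, a$sig, a$eps_r, a$lj_r1, a$coul_r1, a$rc,
                      a$bonds, a$bond_r0, a$bond_k, a$angles, a$theta0,
                      a$angle_k, as.integer(max_steps), initial_step,
                      force_cap, tol, max_step)
  out <- sim_state(res$coords, state$box, state$velocities, state$time)
  attr(out, "energy") <- res$energy
  attr(out, "steps") <- res$steps
  attr(out, "trace") <- res$trace
  out
}

#' Run coarse-grained molecular dynamics
#'
#' Leapfrog integration with optional stochastic velocity rescaling
#' (canonical kinetic-energy sampling, single global coupling) and an
#' optional Berendsen barostat that scales each box axis by the
#' first-order factor computed from the instantaneous pressure tensor
#' diagonal.  Runs are bitwise reproducible for a given
#' `config$seed`.
#'
#' @inheritParams compute_forces
#' @param config an [integrator_config()]
#' @param n_steps number of timesteps
#' @param stride frames/log rows are recorded every `stride` steps
#' @return list of class `md_run` with `trajectory` (a [trajectory()]
#'   over the recorded frames), `log` (data.frame: step, temperature,
#'   energy components, kinetic and total energy, pressure tensor
#'   diagonal, volume) and `state` (final [sim_state()])
#' @export
run_md <- function(state, cg, ff = default_forcefield(),
                   config = integrator_config(), n_steps = 1000,
                   stride = max(1L, n_steps %/% 100L)) {
  a <- .engine_args(cg, ff)
  res <- cpp_run_md(state$coords, state$velocities, state$box,
                    a$mass, a$charge, a$cls, a$eps, a$sig, a$eps_r,
                    a$lj_r1, a$coul_r1, a$rc,
                    a$bonds, a$bond_r0, a$bond_k, a$angles, a$theta0,
                    a$angle_k,
                    config$dt, as.integer(n_steps), as.integer(stride),
                    isTRUE(config$thermostat), config$temperature,
                    config$thermostat_tau,
                    config$barostat == "berendsen", config$p_ref,
                    config$barostat_tau, config$compressibility,
                    config$anisotropic, config$semi_isotropic,
                    config$seed, 10)
  n <- nrow(state$coords)
  nf <- length(res$times)
  coords <- lapply(seq_len(nf), function(k)
    res$frames[((k - 1) * n + 1):(k * n), , drop = FALSE])
  boxes <- lapply(seq_len(nf), function(k) res$boxes[k, ])
  top <- cg$beads
  top$box <- .check_box(state$box)
  traj <- trajectory(top, coords, times = state$time + res$times,
                     boxes = boxes)
  log <- as.data.frame(res$log)
  names(log) <- c("step", "temperature", "e_bond", "e_angle", "e_lj",
                  "e_coulomb", "e_kinetic", "p_xx", "p_yy", "p_zz",
                  "volume", "e_total")
  structure(list(trajectory = traj, log = log,
                 state = sim_state(res$coords, res$box, res$velocities,
                                   state$time + n_steps * config$dt)),
            class = "md_run")
}

#' @export
print.md_run <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("<md_run> %d frames; final T = %.1f K, E = %.1f kJ/mol\n",
              n_frames(x$trajectory), x$log$temperature[n], x$log$e_total[n]))
  invisible(x)
}

# ------------------------------------------------------- emergent analysis

#' Check whether a configuration is a formed bilayer
#'
#' A configuration passes when (i) at least `min_fraction` of the lipids
#' form one distance-connected aggregate, (ii) along one box axis the
#' head/phosphate beads sit clearly outside the tail beads (mean |head
#' offset| exceeding mean |tail offset| by at least `min_separation`:
#' tails interior, heads at the surfaces), (iii) heads populate both
#' sides of the tail slab (two leaflets), and (iv) the aggregate spans
#' the box in the two lateral directions (tail positions laterally
#' delocalized), which distinguishes a periodic slab from a micelle-like
#' blob.
#'
#' @param cg a [cg_model()] containing the lipids (phosphate beads mark
#'   the lipids' headgroups)
#' @param coords coordinates to analyse (default: the model's)
#' @param box box lengths, A
#' @param cluster_cutoff lipid-lipid contact distance for the aggregate
#'   check, A
#' @param min_separation minimum head-tail mean-offset separation along
#'   the normal, A
#' @param max_lateral_concentration maximum circular concentration
#'   (mean resultant length, 0 = uniform, 1 = point) of the tails along
#'   the lateral axes
#' @param min_fraction minimum fraction of lipids in the largest aggregate
#' @return list with `formed` (logical), `axis` (1-3 or NA), `center_z`
#'   (slab center along the axis, A), `fraction` (largest-aggregate
#'   fraction), `separation` (head-tail offset separation per axis),
#'   `lateral_concentration`, `two_leaflets`, `tails_in`
#' @export
detect_bilayer <- function(cg, coords = cg$beads$xyz, box,
                           cluster_cutoff = 7, min_separation = 3,
                           max_lateral_concentration = 0.55,
                           min_fraction = 0.9) {
  if (length(cg$phosphates) < 4) stop("model contains too few lipids")
  res_of <- cg$beads$atoms$res_id
  chain_of <- cg$beads$atoms$chain
  lipid_key <- paste(chain_of[cg$phosphates], res_of[cg$phosphates])
  bead_key <- paste(chain_of, res_of)
  is_lipid_bead <- bead_key %in% lipid_key
  tail <- which(is_lipid_bead & cg$classes == "C")
  head <- cg$phosphates
  # cluster lipids on tail-bead contacts (minimum image)
  lip_ids <- unique(bead_key[tail])
  nl <- length(lip_ids)
  comp <- seq_len(nl)
  tails_by_lip <- split(tail, factor(bead_key[tail], levels = lip_ids))
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (i in seq_len(nl - 1)) {
    xi <- coords[tails_by_lip[[i]], , drop = FALSE]
    for (j in (i + 1):nl) {
      xj <- coords[tails_by_lip[[j]], , drop = FALSE]
      d <- 1e9
      for (r in seq_len(nrow(xi))) {
        dv <- sweep(xj, 2, xi[r, ])
        dv <- dv - sweep(round(sweep(dv, 2, box[1:3], "/")), 2, box[1:3], "*")
        d <- min(d, sqrt(min(rowSums(dv^2))))
      }
      if (d <= cluster_cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  fraction <- max(table(roots)) / nl
  # circular statistics of positions on [0, L)
  circ_rbar <- function(x, L) {
    ang <- 2 * pi * x / L
    sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
  }
  delta <- function(x, c0, L) { d <- x - c0; d - L * round(d / L) }
  # normal axis: where heads sit farthest outside the tails
  separation <- numeric(3); centers <- numeric(3)
  for (ax in 1:3) {
    c0 <- circ_center(coords[tail, ax], box[ax])
    centers[ax] <- c0
    separation[ax] <- mean(abs(delta(coords[head, ax], c0, box[ax]))) -
      mean(abs(delta(coords[tail, ax], c0, box[ax])))
  }
  axis <- which.max(separation)
  lateral <- setdiff(1:3, axis)
  lat_conc <- max(vapply(lateral, function(ax)
    circ_rbar(coords[tail, ax], box[ax]), numeric(1)))
  dh <- delta(coords[head, axis], centers[axis], box[axis])
  two_leaflets <- mean(dh > 0) >= 0.25 && mean(dh < 0) >= 0.25
  tails_in <- separation[axis] > 0
  formed <- fraction >= min_fraction &&
    separation[axis] >= min_separation &&
    lat_conc <= max_lateral_concentration && two_leaflets
  list(formed = formed, axis = if (formed) axis else NA_integer_,
       center_z = centers[axis], fraction = as.numeric(fraction),
       separation = separation, lateral_concentration = lat_conc,
       two_leaflets = two_leaflets, tails_in = tails_in)
}

#' Detect membrane collision and anchoring events in a trajectory
#'
#' A collision event is a maximal run of frames in which any protein bead
#' lies within `contact_cutoff` of any lipid bead.  An event is labeled
#' productive when the anchor beads stay within the headgroup region
#' (|z - bilayer center| <= `head_offset` + `head_margin` along the
#' bilayer normal) for at least `dwell` consecutive frames; the anchoring
#' time is the start of the first productive event.
#'
#' @param traj a [trajectory()] of the protein + membrane system
#' @param cg the matching [cg_model()]
#' @param anchor_beads indices of the anchor-region beads
#' @param contact_cutoff protein-lipid contact distance, A
#' @param dwell minimum number of consecutive in-region frames
#' @param head_margin extra margin beyond the phosphate offset, A
#' @return list with `events` (data.frame: start/end frame, productive),
#'   `anchoring_time` (fs, NA when never productive) and `n_collisions`
#' @export
detect_anchoring <- function(traj, cg, anchor_beads, contact_cutoff = 7,
                             dwell = 3, head_margin = 4) {
  bead_key <- paste(cg$beads$atoms$chain, cg$beads$atoms$res_id)
  lipid_key <- unique(bead_key[cg$phosphates])
  lipid_beads <- which(bead_key %in% lipid_key)
  protein_beads <- setdiff(seq_len(n_atoms(cg$beads)), lipid_beads)
  protein_beads <- setdiff(protein_beads,
                           which(cg$beads$atoms$res_name == "W"))
  nf <- n_frames(traj)
  box <- traj$boxes[[1]][1:3]
  bl <- detect_bilayer(cg, traj$coords[[1]], box)
  if (!bl$formed) {
    bl <- detect_bilayer(cg, traj$coords[[nf]], box)
    if (!bl$formed) stop("analysis error: no bilayer detected in trajectory")
  }
  axis <- bl$axis
  head_off <- stats::median(abs(traj$coords[[1]][cg$phosphates, axis] -
                                  bl$center_z))
  contact <- logical(nf); in_region <- logical(nf)
  for (k in seq_len(nf)) {
    xk <- traj$coords[[k]]
    dmin <- .min_pair_dist(xk[protein_beads, , drop = FALSE],
                           xk[lipid_beads, , drop = FALSE], box)
    contact[k] <- dmin <= contact_cutoff
    cz <- circ_center(xk[lipid_beads, axis], box[axis])
    az <- xk[anchor_beads, axis] - cz
    az <- az - box[axis] * round(az / box[axis])
    in_region[k] <- all(abs(az) <= head_off + head_margin)
  }
  runs <- rle(contact)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ev <- data.frame(start = starts[runs$values], end = ends[runs$values])
  if (nrow(ev)) {
    ev$productive <- vapply(seq_len(nrow(ev)), function(r) {
      reg <- in_region[ev$start[r]:ev$end[r]]
      rr <- rle(reg)
      any(rr$values & rr$lengths >= dwell)
    }, logical(1))
  } else ev$productive <- logical(0)
  t_anchor <- if (any(ev$productive))
    traj$times[ev$start[which(ev$productive)[1]]] else NA_real_
  list(events = ev, anchoring_time = t_anchor, n_collisions = nrow(ev))
}

# minimum-image minimum distance between two coordinate sets
.min_pair_dist <- function(a, b, box) {
  dmin <- Inf
  for (r in seq_len(nrow(a))) {
    dv <- sweep(b, 2, a[r, ])
    dv <- dv - sweep(round(sweep(dv, 2, box, "/")), 2, box, "*")
    dmin <- min(dmin, sqrt(min(rowSums(dv^2))))
  }
  dmin
}

# make a bonded chain contiguous across periodic boundaries by
# minimum-imaging each atom relative to its predecessor (rows must be in
# chain order; a whole-group reference would break chains longer than
# half the box)
.unwrap_group <- function(x, box) {
  if (nrow(x) < 2) return(x)
  for (i in 2:nrow(x)) {
    d <- x[i, ] - x[i - 1, ]
    x[i, ] <- x[i, ] - box * round(d / box)
  }
  x
}

# circular mean position on [0, L)
circ_center <- function(x, L) {
  ang <- 2 * pi * x / L
  (atan2(mean(sin(ang)), mean(cos(ang))) %% (2 * pi)) * L / (2 * pi)
}
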