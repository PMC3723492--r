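# insertion_analysis: quantitative description of protein-membrane
# complexes -- membrane frame, insertion angle/depth, per-residue depth
# tables with class summaries, hydrogen bonds, RMSD/RMSF, z-density
# profiles and an implicit-probe free-energy map.

#' Membrane reference frame of one configuration
#'
#' The bilayer normal is fixed to +z by convention; `center_z` is the
#' mass-weighted center of the lipids along it, and the leaflet phosphate
#' planes are the means of a 2-means split of the phosphate z
#' coordinates.
#'
#' @param s a [structure3d()] (one frame)
#' @param lipid_idx atom indices of all lipid atoms/beads
#' @param phosphate_idx atom indices of the phosphate atoms/beads
#' @param min_separation minimal leaflet separation, A, below which the
#'   leaflets are declared non-separable
#' @return list of class `membrane_frame`: `center_z`, `normal`,
#'   `phosphate_z_upper`, `phosphate_z_lower`
#' @export
membrane_frame <- function(s, lipid_idx, phosphate_idx,
                           min_separation = 6) {
  if (length(phosphate_idx) < 4)
    stop("analysis error: need at least 2 lipids per leaflet")
  center_z <- center_of_mass(s, lipid_idx)[3]
  pz <- s$xyz[phosphate_idx, 3]
  if (diff(range(pz)) < min_separation)
    stop("analysis error: leaflets not separable by z clustering")
  km <- stats::kmeans(pz, centers = range(pz))
  zz <- sort(as.numeric(km$centers))
  if (diff(zz) < min_separation)
    stop("analysis error: leaflets not separable by z clustering")
  structure(list(center_z = center_z, normal = c(0, 0, 1),
                 phosphate_z_upper = zz[2], phosphate_z_lower = zz[1]),
            class = "membrane_frame")
}

#' Insertion angle of a helix with respect to the membrane plane
#'
#' The helix axis is the principal direction (largest singular vector) of
#' the centered CA coordinates; the insertion angle is the angle between
#' that axis and its projection on the membrane surface, folded into
#' [0, 90] degrees (0 = lying flat, 90 = perpendicular).
#'
#' @param s a [structure3d()] (one frame)
#' @param helix_idx indices of the helix CA atoms (>= 4)
#' @param mf a [membrane_frame()]
#' @return angle in degrees
#' @export
insertion_angle <- function(s, helix_idx, mf) {
  if (length(helix_idx) < 4) stop("need at least 4 helix CA atoms")
  x <- s$xyz[helix_idx, , drop = FALSE]
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  if (sv$d[1] < 1e-8) stop("analysis error: degenerate helix axis")
  axis <- sv$v[, 1]
  cos_to_normal <- abs(sum(axis * mf$normal)) / sqrt(sum(axis^2))
  angle_to_normal <- acos(pmin(1, cos_to_normal)) * 180 / pi
  90 - angle_to_normal
}

#' Insertion depth of a residue group
#'
#' Unsigned distance along the bilayer normal between the (mass-weighted)
#' center of mass of the selected atoms and the bilayer center.
#'
#' @param s a [structure3d()] (one frame)
#' @param idx atom indices (non-empty; typically the anchor-residue CAs)
#' @param mf a [membrane_frame()]
#' @return depth in Angstrom
#' @export
insertion_depth <- function(s, idx, mf) {
  if (length(idx) == 0) stop("empty index set")
  abs(center_of_mass(s, idx)[3] - mf$center_z)
}

#' Residue classification used by depth tables
#'
#' Hydrophobic: Ala, Val, Leu, Ile, Pro, Phe, Met, Trp.  Basic: Arg, Lys,
#' His.  Everything else (including Gly and the acidic residues, which
#' interact with headgroups through their polar moieties) is polar.
#'
#' @param res_name three-letter residue name(s)
#' @return character vector in `{"hydrophobic", "basic", "polar"}`
#' @export
residue_class <- function(res_name) {
  up <- toupper(res_name)
  out <- rep("polar", length(up))
  out[up %in% c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")] <-
    "hydrophobic"
  out[up %in% c("ARG", "LYS", "HIS")] <- "basic"
  out
}

#' Per-residue membrane-depth table
#'
#' For each requested residue, the mean and population (divide-by-N)
#' standard deviation over frames of the unsigned distance between the
#' residue's side-chain center of mass and the bilayer center.  Residues
#' without side-chain atoms (glycine, CA traces) fall back to the
#' whole-residue center of mass with a warning.
#'
#' @param traj a [trajectory()]
#' @param res_ids residue ids to tabulate
#' @param mf a single [membrane_frame()] or a list of one per frame
#' @param classes residue classes; default derived via [residue_class()]
#' @param window frame indices to average over (default: all frames)
#' @param whole_residue use the whole-residue center of mass instead of
#'   the side chain
#' @return data.frame of class `depth_table`: `res_id`, `res_name`,
#'   `class`, `mean_depth`, `sd_depth`, with attribute `window`
#' @export
residue_depth_table <- function(traj, res_ids, mf, classes = NULL,
                                window = NULL, whole_residue = FALSE) {
  nf <- n_frames(traj)
  if (is.null(window)) window <- seq_len(nf)
  if (any(window < 1 | window > nf)) stop("window outside trajectory")
  mfl <- if (inherits(mf, "membrane_frame")) rep(list(mf), nf) else mf
  if (length(mfl) != nf) stop("need one membrane frame per trajectory frame")
  atoms <- traj$topology$atoms
  bb_names <- c("N", "CA", "C", "O")
  # protein residues only: lipid/solvent residue ids may collide
  not_protein <- atoms$res_name %in% c("POPC", "TOY", "W", "HOH")
  rows <- lapply(res_ids, function(rid) {
    ridx <- which(atoms$res_id == rid & !not_protein)
    if (length(ridx) == 0) stop("residue ", rid, " not in topology")
    sc <- ridx[!(atoms$name[ridx] %in% bb_names)]
    if (whole_residue || length(sc) == 0) {
      if (length(sc) == 0 && !whole_residue)
        warning("residue ", rid, " has no side-chain atoms; ",
                "using whole-residue center of mass")
      sc <- ridx
    }
    m <- atoms$mass[sc]
    if (sum(m) <= 0) m <- rep(1, length(sc))
    depths <- vapply(window, function(k) {
      z <- sum(traj$coords[[k]][sc, 3] * m) / sum(m)
      abs(z - mfl[[k]]$center_z)
    }, numeric(1))
    data.frame(res_id = rid, res_name = atoms$res_name[ridx[1]],
               mean_depth = mean(depths),
               sd_depth = sqrt(mean((depths - mean(depths))^2)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$class <- if (is.null(classes)) residue_class(out$res_name) else classes
  out <- out[c("res_id", "res_name", "class", "mean_depth", "sd_depth")]
  attr(out, "window") <- window
  class(out) <- c("depth_table", "data.frame")
  out
}

#' Per-class summary of a depth table
#'
#' Arithmetic mean of the row means and of the row standard deviations
#' per residue class.  Published per-residue depth tables print these at
#' one decimal; the summary keeps full precision and leaves rounding to
#' the caller.
#'
#' @param dt a [residue_depth_table()] result, or any data.frame with
#'   columns `class`, `mean_depth`, `sd_depth`
#' @return data.frame: `class`, `mean_depth`, `mean_sd`, `n_residues`
#' @export
group_depth_summary <- function(dt) {
  if (!all(c("class", "mean_depth", "sd_depth") %in% names(dt)))
    stop("need columns class, mean_depth, sd_depth")
  cls <- unique(dt$class)
  empty <- cls[!cls %in% dt$class[!is.na(dt$mean_depth)]]
  if (length(empty)) warning("omitting empty class(es): ",
                             paste(empty, collapse = ", "))
  agg <- lapply(setdiff(cls, empty), function(cl) {
    sub <- dt[dt$class == cl & !is.na(dt$mean_depth), ]
    data.frame(class = cl,
               mean_depth = mean(sub$mean_depth),
               mean_sd = mean(sub$sd_depth),
               n_residues = nrow(sub), stringsAsFactors = FALSE)
  })
  do.call(rbind, agg)
}

#' Reference anchor-region depth statistics
#'
#' Literature-reported per-residue membrane depths (mean +/- sd distance
#' of the surface side-chain center of mass from the bilayer center,
#' last-20-ns averages of six independent atomistic refinement
#' simulations) for the amphipathic anchor region of the iPLA2 catalytic
#' domain.  Used as the reference input for class-level depth summaries.
#'
#' @return data.frame with columns `res_id`, `res_name`, `class`,
#'   `mean_depth`, `sd_depth`
#' @export
anchor_depth_reference <- function() {
  data.frame(
    res_id = c(711, 714, 715, 717, 721, 722, 710, 719,
               712, 713, 716, 720, 723),
    res_name = c("PRO", "PRO", "TRP", "LEU", "VAL", "PHE", "ARG", "LYS",
                 "SER", "ASN", "GLU", "THR", "GLY"),
    class = c(rep("hydrophobic", 6), rep("basic", 2), rep("polar", 5)),
    mean_depth = c(16.8, 16.4, 15.0, 19.0, 15.2, 13.7, 19.0, 18.3,
                   19.4, 20.6, 20.7, 17.2, 18.9),
    sd_depth = c(1.9, 2.0, 1.7, 2.2, 1.6, 1.6, 2.2, 1.6,
                 1.8, 2.0, 1.7, 2.0, 1.6),
    stringsAsFactors = FALSE)
}

#' Count protein-lipid hydrogen bonds in one configuration
#'
#' Geometric criterion: donor-acceptor distance <= `dist_cutoff` and
#' donor-H-acceptor angle >= `angle_min` (default 3.5 A / 150 degrees).
#' With `heavy_only = TRUE` only the distance criterion applies (for
#' models without hydrogens).
#'
#' @param s a [structure3d()] (one frame)
#' @param donors two-column matrix `(heavy donor index, attached hydrogen
#'   index)`; with `heavy_only = TRUE`, a plain index vector
#' @param acceptors acceptor atom indices
#' @param dist_cutoff donor-acceptor distance cutoff, A
#' @param angle_min minimum D-H-A angle, degrees
#' @param heavy_only ignore hydrogens and use the distance criterion only
#' @return integer hydrogen-bond count
#' @export
hbond_count <- function(s, donors, acceptors, dist_cutoff = 3.5,
                        angle_min = 150, heavy_only = FALSE) {
  if (!heavy_only && (is.null(dim(donors)) || ncol(donors) != 2))
    stop("donors must be a (heavy, hydrogen) index matrix; ",
         "for models without hydrogens use heavy_only = TRUE")
  if (heavy_only) donors <- cbind(as.integer(donors), NA_integer_)
  count <- 0L
  for (r in seq_len(nrow(donors))) {
    d <- donors[r, 1]
    dv <- sweep(s$xyz[acceptors, , drop = FALSE], 2, s$xyz[d, ])
    dist <- sqrt(rowSums(dv^2))
    ok <- dist <= dist_cutoff & dist > 0
    if (!heavy_only && any(ok)) {
      h <- donors[r, 2]
      hv <- s$xyz[d, ] - s$xyz[h, ]
      for (ia in which(ok)) {
        av <- s$xyz[acceptors[ia], ] - s$xyz[h, ]
        cosang <- sum(hv * av) / sqrt(sum(hv^2) * sum(av^2))
        # D-H-A angle: vectors from H to D and from H to A
        ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
        if (ang < angle_min) ok[ia] <- FALSE
      }
    }
    count <- count + sum(ok)
  }
  count
}

#' RMSD time series and RMSF profile
#'
#' `rmsd_series()` returns the per-frame root-mean-square deviation of
#' the selected atoms from a reference, optionally after a Kabsch fit.
#' `rmsf_profile()` fits every frame onto the time-mean structure
#' (two-pass) and returns per-atom root-mean-square fluctuations about
#' the mean.
#'
#' @param traj a [trajectory()]
#' @param ref reference [structure3d()] (defaults to frame 1)
#' @param idx atom indices to superpose and measure
#' @param fit apply a least-squares fit before each RMSD
#' @return `rmsd_series()`: numeric vector (A) per frame;
#'   `rmsf_profile()`: numeric vector (A) per selected atom
#' @export
rmsd_series <- function(traj, ref = NULL, idx = NULL, fit = TRUE) {
  if (is.null(ref)) ref <- frame_structure(traj, 1)
  if (is.null(idx)) idx <- seq_len(n_atoms(ref))
  rx <- ref$xyz[idx, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(k) {
    x <- traj$coords[[k]][idx, , drop = FALSE]
    if (fit) x <- apply_transform(x, kabsch_fit(x, rx))
    sqrt(mean(rowSums((x - rx)^2)))
  }, numeric(1))
}

#' @rdname rmsd_series
#' @export
rmsf_profile <- function(traj, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(n_atoms(traj$topology))
  nf <- n_frames(traj)
  first <- traj$coords[[1]][idx, , drop = FALSE]
  fitted <- lapply(seq_len(nf), function(k) {
    x <- traj$coords[[k]][idx, , drop = FALSE]
    apply_transform(x, kabsch_fit(x, first))
  })
  mean_x <- Reduce(`+`, fitted) / nf
  fitted <- lapply(fitted, function(x) apply_transform(x, kabsch_fit(x, mean_x)))
  mean_x <- Reduce(`+`, fitted) / nf
  dev2 <- Reduce(`+`, lapply(fitted, function(x) rowSums((x - mean_x)^2))) / nf
  sqrt(dev2)
}

#' Mass-weighted z-density profiles around the bilayer center
#'
#' Per-group histograms of atom z positions relative to the bilayer
#' center, mass-weighted and normalized so each profile integrates to 1.
#'
#' @param traj a [trajectory()]
#' @param groups named list of atom index vectors
#' @param mf a [membrane_frame()] or list of one per frame
#' @param bin_width histogram bin width, A
#' @param range z range (relative to the bilayer center) to cover;
#'   defaults to symmetric coverage of the first frame's box
#' @return list with `mids` (bin centers, A) and `density` (matrix,
#'   groups x bins, integrating to 1 per group)
#' @export
density_profile <- function(traj, groups, mf, bin_width = 1,
                            range = NULL) {
  nf <- n_frames(traj)
  mfl <- if (inherits(mf, "membrane_frame")) rep(list(mf), nf) else mf
  if (is.null(range)) {
    L <- traj$boxes[[1]][3]
    range <- c(-L / 2, L / 2)
  }
  breaks <- seq(range[1], range[2] + bin_width, by = bin_width)
  mids <- breaks[-1] - bin_width / 2
  masses <- traj$topology$atoms$mass
  dens <- matrix(0, length(groups), length(mids),
                 dimnames = list(names(groups), NULL))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    if (length(idx) == 0) {
      warning("empty group '", names(groups)[g], "'; flat zero profile")
      next
    }
    m <- masses[idx]
    if (sum(m) <= 0) m <- rep(1, length(idx))
    acc <- numeric(length(mids))
    for (k in seq_len(nf)) {
      z <- traj$coords[[k]][idx, 3] - mfl[[k]]$center_z
      bin <- findInterval(z, breaks, rightmost.closed = TRUE)
      keep <- bin >= 1 & bin <= length(mids)
      acc <- acc + tapply_add(bin[keep], m[keep], length(mids))
    }
    total <- sum(acc) * bin_width
    if (total > 0) dens[g, ] <- acc / total
  }
  list(mids = mids, density = dens)
}

#' Implicit-probe free-energy map
#'
#' Boltzmann-averaged insertion free energy of a single-site apolar probe
#' (methane-like) over an unperturbed trajectory:
#' `F(x) = -kB T log( mean_frames exp(-dE(x)/kB T) )`, with `dE` the
#' shifted 12-6 LJ interaction between the probe and all atoms within
#' 12 A of the voxel.  Voxels never sampled return `Inf`.
#'
#' @param traj a [trajectory()] whose frames share one box
#' @param probe_epsilon,probe_sigma probe LJ parameters (kJ mol^-1, A)
#' @param spacing grid spacing, A (must be >= 0.1; finer grids are
#'   refused as a resource guard)
#' @param temperature K
#' @param origin,extent grid origin and extent, A (default: the box)
#' @return list with `x`, `y`, `z` (voxel center vectors) and `F`
#'   (3-D array of free energies, kJ mol^-1)
#' @export
ils_map <- function(traj, probe_epsilon = 1.2, probe_sigma = 3.7,
                    spacing = 2, temperature = 323,
                    origin = c(0, 0, 0), extent = NULL) {
  if (spacing < 0.1) stop("grid spacing below 0.1 A refused (resource guard)")
  if (is.null(extent)) extent <- traj$boxes[[1]][1:3]
  gx <- seq(origin[1] + spacing / 2, origin[1] + extent[1], by = spacing)
  gy <- seq(origin[2] + spacing / 2, origin[2] + extent[2], by = spacing)
  gz <- seq(origin[3] + spacing / 2, origin[3] + extent[3], by = spacing)
  vox <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  kT <- .kB * temperature
  nf <- n_frames(traj)
  acc <- numeric(nrow(vox))
  for (k in seq_len(nf)) {
    xk <- traj$coords[[k]]
    dE <- numeric(nrow(vox))
    for (a in seq_len(nrow(xk))) {
      dv <- sweep(vox, 2, xk[a, ])
      r2 <- rowSums(dv^2)
      near <- which(r2 < 144 & r2 > 1e-12)
      if (length(near)) {
        lj <- lj_shifted(sqrt(r2[near]), probe_epsilon, probe_sigma)
        dE[near] <- dE[near] + lj$energy
      }
    }
    acc <- acc + exp(-dE / kT)
  }
  Fv <- ifelse(acc > 0, -kT * log(acc / nf), Inf)
  list(x = gx, y = gy, z = gz,
       F = array(Fv, dim = c(length(gx), length(gy), length(gz))))
}
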