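# backmapper: reconstruct an atomistic protein-membrane system from an
# equilibrated CG complex -- rigid-body least-squares fit of an atomistic
# reference onto the CG backbone beads, alignment of an equilibrated
# membrane patch onto the CG phosphates, clash pruning, lattice solvation
# with ionization, and a declarative water-exclusion region for the gap
# between protein and membrane.

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation + translation minimizing the RMSD between two
#' paired point sets (SVD solution with determinant sign correction, so an
#' improper rotation is never returned).
#'
#' @param mobile `n x 3` matrix of points to move
#' @param target `n x 3` matrix of reference points (same `n`, >= 3,
#'   not all collinear)
#' @return list of class `rigid_transform`: `rotation` (3x3,
#'   det = +1), `translation` (length 3), `rmsd_after` (A).  Apply with
#'   [apply_transform()].
#' @export
kabsch_fit <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target))
    stop("mobile and target must contain the same number of points")
  if (nrow(mobile) < 3) stop("at least 3 points are required")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  if (all(svd(A)$d[2:3] < 1e-10)) stop("degenerate (collinear) point set")
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  structure(list(rotation = R, translation = as.numeric(ct - R %*% cm),
                 rmsd_after = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates or a structure
#' @param x `n x 3` matrix or a [structure3d()]
#' @param tr a `rigid_transform` from [kabsch_fit()]
#' @return object of the same type, transformed
#' @export
apply_transform <- function(x, tr) {
  if (inherits(x, "mem_structure")) {
    x$xyz <- apply_transform(x$xyz, tr)
    return(x)
  }
  sweep(as.matrix(x) %*% t(tr$rotation), 2, tr$translation, "+")
}

#' Fit an atomistic protein onto CG backbone beads
#'
#' Rigid-body move of the whole atomistic structure by the Kabsch
#' transform between its CA atoms and the CG backbone beads, paired by
#' residue id.  Internal geometry is untouched (pure rotation +
#' translation).
#'
#' @param aa_ref atomistic reference [structure3d()] (one CA per residue)
#' @param cg equilibrated [cg_model()] of the same protein
#' @return the moved `aa_ref`, with attribute `transform`
#' @export
fit_protein_to_cg <- function(aa_ref, cg) {
  ca <- select_atoms(aa_ref, "name CA")
  ca_res <- aa_ref$atoms$res_id[ca]
  bb <- cg$backbone
  bb_res <- cg$beads$atoms$res_id[bb]
  common <- intersect(ca_res, bb_res)
  missing <- setdiff(union(ca_res, bb_res), common)
  if (length(missing))
    stop("mapping error: residues without CA/backbone-bead counterpart: ",
         paste(sort(missing), collapse = ", "))
  ca <- ca[match(common, ca_res)]
  bb <- bb[match(common, bb_res)]
  tr <- kabsch_fit(aa_ref$xyz[ca, , drop = FALSE],
                   cg$beads$xyz[bb, , drop = FALSE])
  out <- apply_transform(aa_ref, tr)
  attr(out, "transform") <- tr
  out
}

#' Align a membrane patch onto CG phosphate positions
#'
#' The patch (a pre-equilibrated bilayer) is translated so that its
#' phosphate center of mass and mean bilayer plane coincide with those of
#' the CG phosphates; no rotation is applied by default (the phosphate
#' clouds define no point correspondence), and leaflet spacing is
#' preserved exactly.
#'
#' @param patch bilayer [structure3d()] whose phosphorus/phosphate atoms
#'   are identified by `patch_selection`
#' @param cg_phosphates `m x 3` matrix of CG phosphate coordinates
#' @param patch_selection selection expression for the patch's phosphate
#'   atoms (default `"name P or name PO4 or name HD"`)
#' @return the translated patch, with attribute `translation`
#' @export
fit_membrane_to_cg <- function(patch, cg_phosphates,
                               patch_selection = "name P or name PO4 or name HD") {
  idx <- select_atoms(patch, patch_selection)
  if (length(idx) < 4) stop("analysis error: patch has too few phosphate atoms")
  pz <- patch$xyz[idx, 3]
  if (diff(range(pz)) < 5)
    stop("analysis error: patch is not bilayer-like (no two phosphate z-modes)")
  km <- stats::kmeans(pz, centers = range(pz))
  if (abs(diff(km$centers)) < 5)
    stop("analysis error: patch is not bilayer-like (no two phosphate z-modes)")
  cg_phosphates <- as.matrix(cg_phosphates)
  shift <- colMeans(cg_phosphates) - colMeans(patch$xyz[idx, , drop = FALSE])
  patch$xyz <- sweep(patch$xyz, 2, shift, "+")
  attr(patch, "translation") <- as.numeric(shift)
  patch
}

#' Remove lipids clashing with the protein
#'
#' A lipid is removed in full if any of its atoms lies strictly within
#' `cutoff` of any protein atom; all other atoms are untouched.
#'
#' @param system [structure3d()] containing the lipids
#' @param protein [structure3d()] of the placed protein
#' @param cutoff clash distance, A (default 0.6)
#' @param lipid_resnames residue names identifying lipids
#' @return the pruned system, with attribute `removed` (lipid count)
#' @export
prune_lipids <- function(system, protein, cutoff = 0.6,
                         lipid_resnames = c("POPC", "TOY")) {
  is_lip <- system$atoms$res_name %in% lipid_resnames
  lip_key <- paste(system$atoms$chain, system$atoms$res_id)
  clash_key <- character(0)
  if (any(is_lip)) {
    lx <- system$xyz[is_lip, , drop = FALSE]
    # block distance computation, no PBC (patch and protein share a frame)
    d2min <- rep(Inf, nrow(lx))
    for (r in seq_len(n_atoms(protein))) {
      dv <- sweep(lx, 2, protein$xyz[r, ])
      d2min <- pmin(d2min, rowSums(dv^2))
    }
    clash_key <- unique(lip_key[is_lip][d2min < cutoff^2])
  }
  keep <- !(is_lip & lip_key %in% clash_key)
  out <- subset_structure(system, which(keep))
  attr(out, "removed") <- length(clash_key)
  out
}

#' Solvate a system on a lattice and add ions
#'
#' Waters (single-site placeholders named OW) are placed on a cubic
#' lattice inside the box, skipping sites within `exclusion` of any
#' solute atom.  The ion count per species is
#' `round(conc * N_A * V_solvent)` with `V_solvent` the volume of the
#' placed waters, plus counter-ions to neutralize the net system charge;
#' ions replace randomly chosen waters (seeded).
#'
#' @param system solvated-to-be [structure3d()] with a box
#' @param target_conc salt concentration, mol/L (default 0.1)
#' @param exclusion solute exclusion radius, A
#' @param spacing water lattice spacing, A
#' @param seed integer seed for the water -> ion replacement
#' @return the solvated system, with attributes `n_waters`, `n_ions`
#'   (per species: `NA.` = cations, `CL` = anions)
#' @export
solvate_and_ionize <- function(system, target_conc = 0.1, exclusion = 2.4,
                               spacing = 3.1, seed = 1L) {
  if (is.null(system$box)) stop("system needs a box to solvate")
  box <- system$box[1:3]
  g <- as.matrix(expand.grid(
    x = seq(spacing / 2, box[1] - spacing / 4, by = spacing),
    y = seq(spacing / 2, box[2] - spacing / 4, by = spacing),
    z = seq(spacing / 2, box[3] - spacing / 4, by = spacing)))
  keep <- rep(TRUE, nrow(g))
  for (r in seq_len(n_atoms(system))) {
    dv <- sweep(g, 2, system$xyz[r, ])
    dv <- dv - sweep(round(sweep(dv, 2, box, "/")), 2, box, "*")
    keep <- keep & rowSums(dv^2) >= exclusion^2
  }
  g <- g[keep, , drop = FALSE]
  nw <- nrow(g)
  v_water <- 1e27 / (55.34 * 6.02214076e23)  # A^3 per liquid water
  v_solvent <- nw * v_water
  n_salt <- as.integer(round(target_conc * 6.02214076e23 * v_solvent * 1e-27))
  net_q <- as.integer(round(sum(system$atoms$charge)))
  n_pos <- n_salt + max(0L, -net_q)
  n_neg <- n_salt + max(0L, net_q)
  if (n_pos + n_neg > nw)
    stop("build error: not enough water sites for the requested ions")
  set.seed(seed)
  ion_sites <- sample.int(nw, n_pos + n_neg)
  water_sites <- setdiff(seq_len(nw), ion_sites)
  maxres <- if (n_atoms(system)) max(system$atoms$res_id) else 0L
  mk <- function(sites, name, resn, el, mass, q, res0) {
    if (length(sites) == 0) return(NULL)
    structure3d(
      data.frame(name = name, element = el, res_name = resn,
                 res_id = res0 + seq_along(sites), chain = "S",
                 mass = mass, charge = q, is_bead = FALSE,
                 stringsAsFactors = FALSE),
      g[sites, , drop = FALSE], box = system$box)
  }
  wat <- mk(water_sites, "OW", "HOH", "O", 18.015, 0, maxres)
  pos <- mk(ion_sites[seq_len(n_pos)], "NA", "NA", "NA", 22.99, 1,
            maxres + length(water_sites))
  neg <- mk(ion_sites[n_pos + seq_len(n_neg)], "CL", "CL", "CL", 35.45, -1,
            maxres + length(water_sites) + n_pos)
  out <- do.call(combine_structures,
                 c(list(system), Filter(Negate(is.null), list(wat, pos, neg)),
                   list(box = system$box)))
  attr(out, "n_waters") <- length(water_sites)
  attr(out, "n_ions") <- c(`NA.` = n_pos, CL = n_neg)
  out
}

#' Water-exclusion region between protein and membrane
#'
#' Emits a declarative region -- a z-slab bounded below by the proximal
#' membrane phosphate plane and above by the protein's lower envelope,
#' clipped laterally to the protein footprint -- plus a half-harmonic
#' repulsive wall constant.  Solvation builders and external engines can
#' use it to keep water out of the protein-membrane gap.
#'
#' @param protein placed [structure3d()]
#' @param membrane placed [structure3d()] of the bilayer
#' @param wall_k half-harmonic wall force constant, kJ mol^-1 A^-2
#' @param phosphate_selection selection for the membrane phosphate plane
#' @return list of class `exclusion_region`: `z_bottom`, `z_top`,
#'   `center_xy`, `radius`, `wall_k`, `empty`.  Serialize with
#'   [write_region()].
#' @export
water_exclusion_region <- function(protein, membrane, wall_k = 10,
                                   phosphate_selection = "name P or name PO4 or name HD") {
  pidx <- select_atoms(membrane, phosphate_selection)
  if (length(pidx) == 0) pidx <- seq_len(n_atoms(membrane))
  pz <- membrane$xyz[pidx, 3]
  mid <- mean(range(pz))
  upper <- mean(pz[pz > mid])
  # protein lower envelope within its lateral footprint
  z_low <- min(protein$xyz[, 3])
  cxy <- colMeans(protein$xyz[, 1:2, drop = FALSE])
  radius <- max(sqrt(rowSums(sweep(protein$xyz[, 1:2, drop = FALSE],
                                   2, cxy)^2))) + 2
  if (z_low <= upper) {
    warning("protein touches or enters the membrane; empty exclusion region")
    return(structure(list(z_bottom = upper, z_top = upper,
                          center_xy = cxy, radius = radius,
                          wall_k = wall_k, empty = TRUE),
                     class = "exclusion_region"))
  }
  structure(list(z_bottom = upper, z_top = z_low, center_xy = cxy,
                 radius = radius, wall_k = wall_k, empty = FALSE),
            class = "exclusion_region")
}

#' Serialize an exclusion region to YAML
#' @param region an `exclusion_region`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_region <- function(region, path) {
  yaml::write_yaml(list(
    type = "z_slab",
    z_bottom = region$z_bottom, z_top = region$z_top,
    center_x = region$center_xy[1], center_y = region$center_xy[2],
    radius = region$radius, wall_k = region$wall_k,
    empty = region$empty), path)
  invisible(path)
}
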