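# fixtures: generators for every synthetic input -- ideal/amphipathic
# helices, toy lipids, pre-assembled bilayers, random self-assembly boxes,
# a miniature iPLA2-like anchor protein and synthetic deuterium-exchange
# tables -- so all other modules are testable without external data.

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' The anchor-region sequence used by the fixtures
#'
#' Fifteen residues numbered 710-724 in full-protein coordinates:
#' basic Arg710/Lys719, the hydrophobic cluster Pro711, Pro714, Trp715,
#' Leu717, Val721, Phe722 on one helix face, and polar Ser712, Asn713,
#' Glu716, Thr720, Gly723 on the other -- the composition of the
#' iPLA2 amphipathic membrane anchor.
#'
#' @return one-letter sequence string
#' @export
anchor_sequence <- function() "RPSNPWELAKTVFGS"

#' Build an ideal helix as a CA trace with side-chain pseudo-atoms
#'
#' CA atom `i` sits at azimuth `i * twist` and height `i * rise` on a
#' cylinder of the given radius (textbook alpha-helix defaults: 1.5 A
#' rise, 100 degrees twist, 2.3 A radius).  Every non-glycine residue
#' gets a single side-chain pseudo-atom (`SC`) placed radially outward,
#' so amphipathic sequences expose their hydrophobic face geometrically.
#'
#' @param sequence one-letter amino-acid string
#' @param rise helical rise per residue, A (> 0)
#' @param twist helical twist per residue, degrees (0 < twist < 360)
#' @param radius CA cylinder radius, A
#' @param resid_start first residue id (so full-protein numbering such as
#'   710-724 can be reproduced)
#' @param sc_offset radial offset of the side-chain pseudo-atom beyond
#'   the CA radius, A
#' @return a [structure3d()] (helix axis along +z, base at the origin)
#' @export
build_helix <- function(sequence, rise = 1.5, twist = 100, radius = 2.3,
                        resid_start = 1L, sc_offset = 3) {
  if (rise <= 0) stop("rise must be > 0")
  if (twist <= 0 || twist >= 360) stop("twist must lie in (0, 360)")
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!all(letters1 %in% names(.AA3)))
    stop("unknown residue letter(s): ",
         paste(unique(letters1[!letters1 %in% names(.AA3)]), collapse = ""))
  n <- length(letters1)
  rows <- list(); xyz <- list(); k <- 0L
  for (i in seq_len(n)) {
    ang <- (i - 1) * twist * pi / 180
    z <- (i - 1) * rise
    rid <- resid_start + i - 1L
    rn <- .AA3[[letters1[i]]]
    k <- k + 1L
    rows[[k]] <- data.frame(name = "CA", element = "C", res_name = rn,
                            res_id = rid, chain = "A", mass = 56,
                            charge = 0, is_bead = FALSE,
                            stringsAsFactors = FALSE)
    xyz[[k]] <- c(radius * cos(ang), radius * sin(ang), z)
    if (!(rn %in% c("GLY", "ALA"))) {  # no side-chain bead in the template
      k <- k + 1L
      rows[[k]] <- data.frame(name = "SC1", element = "X", res_name = rn,
                              res_id = rid, chain = "A", mass = 50,
                              charge = 0, is_bead = FALSE,
                              stringsAsFactors = FALSE)
      xyz[[k]] <- c((radius + sc_offset) * cos(ang),
                    (radius + sc_offset) * sin(ang), z)
    }
  }
  structure3d(do.call(rbind, rows), do.call(rbind, xyz),
              title = "ideal helix fixture")
}

#' Build a pre-assembled toy bilayer
#'
#' `2 * nx * ny` three-bead toy lipids on two leaflet grids: head beads at
#' `+/- head_offset` from the midplane (z = `center_z`), tails pointing
#' inward, lateral spacing `sqrt(apl)`.  The box is sized to the leaflet
#' grid laterally and `box_z` along the normal.
#'
#' @param nx,ny lipids per leaflet dimension (>= 1)
#' @param apl area per lipid, A^2
#' @param head_offset distance of the head/phosphate plane from the
#'   midplane, A
#' @param center_z z position of the bilayer midplane, A
#' @param box_z box height, A
#' @param jitter lateral position jitter (A, seeded by `seed`)
#' @param seed integer seed for the jitter
#' @return a [structure3d()] of TOY residues (atoms HD, TL1, TL2)
#' @export
build_bilayer <- function(nx = 6, ny = 6, apl = 28, head_offset = 12,
                          center_z = NULL, box_z = 48, jitter = 0.3,
                          seed = 1L) {
  if (nx < 1 || ny < 1) stop("nx and ny must be >= 1")
  if (apl <= 0 || head_offset <= 0) stop("apl and head_offset must be > 0")
  a <- sqrt(apl)
  box <- c(nx * a, ny * a, box_z)
  if (is.null(center_z)) center_z <- box_z / 2
  set.seed(seed)
  rows <- list(); xyz <- list(); k <- 0L; rid <- 0L
  spacing <- 4.7
  for (leaf in c(1, -1)) {
    for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
      rid <- rid + 1L
      x0 <- (ix - 0.5) * a + stats::rnorm(1, 0, jitter)
      y0 <- (iy - 0.5) * a + stats::rnorm(1, 0, jitter)
      zs <- center_z + leaf * (head_offset - c(0, 1, 2) * spacing)
      for (b in 1:3) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          name = c("HD", "TL1", "TL2")[b], element = "X",
          res_name = "TOY", res_id = rid, chain = "L", mass = 72,
          charge = 0, is_bead = FALSE, stringsAsFactors = FALSE)
        xyz[[k]] <- c(x0, y0, zs[b])
      }
    }
  }
  structure3d(do.call(rbind, rows), do.call(rbind, xyz), box = box,
              title = "toy bilayer fixture")
}

#' Random self-assembly box
#'
#' Uniformly random, seeded placement of straight three-bead toy lipids
#' and coarse water sites (plus an optional solute centered in the box),
#' emulating the protocol of simulating membrane self-assembly from a
#' random lipid configuration around a protein.  Overlaps are left for
#' the clash-capped minimizer to resolve; a density guard refuses boxes
#' that could not relax.
#'
#' @param n_lipids number of toy lipids
#' @param n_waters number of coarse water sites
#' @param box box lengths (length 1 or 3), A
#' @param solute optional [structure3d()] placed at the box center
#' @param seed integer seed
#' @return a [structure3d()] (TOY lipids, W water sites, solute atoms)
#' @export
random_box <- function(n_lipids, n_waters, box, solute = NULL, seed = 1L) {
  box <- rep(as.numeric(box), length.out = 3)
  n_solute <- if (is.null(solute)) 0L else n_atoms(solute)
  n_sites <- 3 * n_lipids + n_waters + n_solute
  if (n_sites * 104 > 1.25 * prod(box))
    stop("build error: requested contents exceed the box density limit")
  set.seed(seed)
  rows <- list(); xyz <- list(); k <- 0L
  for (l in seq_len(n_lipids)) {
    origin <- stats::runif(3) * box
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    for (b in 1:3) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        name = c("HD", "TL1", "TL2")[b], element = "X", res_name = "TOY",
        res_id = l, chain = "L", mass = 72, charge = 0, is_bead = FALSE,
        stringsAsFactors = FALSE)
      xyz[[k]] <- (origin + (b - 1) * 4.7 * u) %% box
    }
  }
  for (w in seq_len(n_waters)) {
    k <- k + 1L
    rows[[k]] <- data.frame(
      name = "W", element = "X", res_name = "W", res_id = w,
      chain = "W", mass = 72.06, charge = 0, is_bead = FALSE,
      stringsAsFactors = FALSE)
    xyz[[k]] <- stats::runif(3) * box
  }
  out <- structure3d(do.call(rbind, rows), do.call(rbind, xyz), box = box,
                     title = "random self-assembly box")
  if (!is.null(solute)) {
    shift <- box / 2 - colMeans(solute$xyz)
    solute$xyz <- sweep(solute$xyz, 2, shift, "+")
    solute$box <- .check_box(box)
    out <- combine_structures(solute, out, box = .check_box(box))
  }
  out
}

#' Coarse-grain a fixture structure
#'
#' Maps every component of a fixture system to beads: protein residues
#' through the packaged protein templates (plus an elastic network),
#' TOY lipids through the 3-bead toy template, and W sites to water
#' beads.  Bead order is protein, lipids, water.
#'
#' @param s a fixture [structure3d()]
#' @param enm_cutoff,enm_k elastic-network parameters (A, kJ mol^-1
#'   A^-2); `enm_cutoff = 0` disables the network
#' @return a [cg_model()] carrying the structure's box
#' @export
fixture_cg <- function(s, enm_cutoff = 7, enm_k = 10) {
  is_prot <- s$atoms$res_name %in% .AA3
  is_lip <- s$atoms$res_name == "TOY"
  is_wat <- s$atoms$res_name == "W"
  parts <- list()
  if (any(is_prot)) {
    p <- map_protein(subset_structure(s, which(is_prot)))
    if (enm_cutoff > 0) p <- with_elastic_network(p, enm_cutoff, enm_k)
    parts <- c(parts, list(p))
  }
  if (any(is_lip)) {
    parts <- c(parts, list(map_lipid(subset_structure(s, which(is_lip)),
                                     lipid_template("toy3"))))
  }
  if (any(is_wat)) {
    ws <- subset_structure(s, which(is_wat))
    ws$atoms$is_bead <- TRUE
    ws$atoms$name <- "W"
    parts <- c(parts, list(cg_model(ws, rep("P", n_atoms(ws)))))
  }
  do.call(combine_cg, c(parts, list(box = s$box)))
}

# rotate helix so its axis lies along +x and the mean direction of the
# hydrophobic side chains (optionally restricted to a residue range,
# e.g. the anchor helix) points along -z
.orient_amphipathic <- function(helix, resid_range = NULL) {
  # axis z -> x
  Ry <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3)
  helix$xyz <- helix$xyz %*% t(Ry)
  hyd <- which(helix$atoms$name == "SC1" &
                 residue_class(helix$atoms$res_name) == "hydrophobic")
  if (!is.null(resid_range))
    hyd <- hyd[helix$atoms$res_id[hyd] %in% resid_range]
  ca <- match(helix$atoms$res_id[hyd], helix$atoms$res_id[helix$atoms$name == "CA"])
  ca_idx <- which(helix$atoms$name == "CA")[ca]
  v <- helix$xyz[hyd, c(2, 3), drop = FALSE] - helix$xyz[ca_idx, c(2, 3), drop = FALSE]
  ang <- atan2(mean(v[, 2]), mean(v[, 1]))
  rot <- -pi / 2 - ang  # bring mean azimuth to -z
  Rx <- matrix(c(1, 0, 0,
                 0, cos(rot), -sin(rot),
                 0, sin(rot), cos(rot)), 3, 3, byrow = TRUE)
  helix$xyz <- helix$xyz %*% t(Rx)
  helix
}

#' Miniature iPLA2-like anchor protein
#'
#' A 40-residue helix-loop-helix fixture numbered 706-745 in full-protein
#' coordinates: a short N-terminal linker, the amphipathic anchor helix
#' 710-724 lying in the membrane plane (hydrophobic face down), and a
#' "long helix" 725-745 rising out of the interface at `tilt` degrees.
#' In the `"membrane"` pose the anchor side chains sit below the given
#' phosphate plane; in the `"solution"` pose the whole protein floats
#' `solution_gap` above it.
#'
#' @param pose `"membrane"` or `"solution"`
#' @param phosphate_z z of the proximal phosphate plane, A
#' @param center_xy lateral position of the anchor center, A
#' @param tilt insertion angle of the long helix, degrees
#' @param anchor_depth how far below `phosphate_z` the anchor CA axis
#'   sits in the membrane pose, A
#' @param solution_gap gap above `phosphate_z` in the solution pose, A
#' @return a [structure3d()] (CA trace + side-chain pseudo-atoms)
#' @export
toy_protein <- function(pose = c("membrane", "solution"),
                        phosphate_z = 12, center_xy = c(0, 0), tilt = 67,
                        anchor_depth = 4, solution_gap = 10) {
  pose <- match.arg(pose)
  seqs <- paste0("GSGS", anchor_sequence(), "AELKALEQKLAELKSELAQKA")
  helix <- build_helix(seqs, resid_start = 706L)
  helix <- .orient_amphipathic(helix, resid_range = 710:724)
  long_idx <- which(helix$atoms$res_id >= 725)
  anchor_ca <- which(helix$atoms$res_id %in% 710:724 &
                       helix$atoms$name == "CA")
  pivot <- helix$xyz[max(anchor_ca), ]
  th <- -tilt * pi / 180  # row-vector convention: negative angle tilts +z
  Ry <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
               3, 3, byrow = TRUE)
  helix$xyz[long_idx, ] <- sweep(
    sweep(helix$xyz[long_idx, , drop = FALSE], 2, pivot) %*% t(Ry),
    2, pivot, "+")
  z_target <- if (pose == "membrane") phosphate_z - anchor_depth else
    phosphate_z + solution_gap + anchor_depth
  shift <- c(center_xy, z_target) - c(
    mean(helix$xyz[anchor_ca, 1]), mean(helix$xyz[anchor_ca, 2]),
    mean(helix$xyz[anchor_ca, 3]))
  helix$xyz <- sweep(helix$xyz, 2, shift, "+")
  helix$title <- sprintf("toy anchor protein (%s pose)", pose)
  helix
}

#' Synthetic deuterium-exchange fragment table
#'
#' Builds a DXMS table from `(range, decrement, incubation)` records, or
#' from the packaged `"ipla2"` preset that reproduces the published
#' exchange pattern for the iPLA2 catalytic domain: one strongly
#' protected fragment (708-730, 70% decrement at 5 min) and three weakly
#' protected cavity fragments (631-655, 658-664, 773-778, <40%).
#'
#' @param regions list of `list(range = c(start, end), decrement_pct,
#'   incubation_s)` records with non-overlapping ranges; ignored when a
#'   preset is named
#' @param preset `NULL` or `"ipla2"`
#' @return fragment data.frame (see [read_dxms()] for columns)
#' @export
synth_dxms <- function(regions = list(), preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "ipla2")
    regions <- list(
      list(range = c(708, 730), decrement_pct = 70, incubation_s = 300),
      list(range = c(631, 655), decrement_pct = 30, incubation_s = 300),
      list(range = c(658, 664), decrement_pct = 25, incubation_s = 300),
      list(range = c(773, 778), decrement_pct = 35, incubation_s = 300))
  }
  if (length(regions) == 0) {
    return(data.frame(res_start = integer(0), res_end = integer(0),
                      decrement_pct = numeric(0), incubation_s = numeric(0)))
  }
  df <- do.call(rbind, lapply(regions, function(r)
    data.frame(res_start = r$range[1], res_end = r$range[2],
               decrement_pct = r$decrement_pct,
               incubation_s = r$incubation_s)))
  df <- df[order(df$res_start), , drop = FALSE]
  if (nrow(df) > 1 && any(df$res_start[-1] <= df$res_end[-nrow(df)]))
    stop("fragment ranges must not overlap")
  rownames(df) <- NULL
  df
}

#' Solvate a fixture system with coarse water sites
#'
#' Adds W sites on a jittered cubic lattice, skipping sites within
#' `exclusion` of any existing atom (minimum-image).
#'
#' @param s fixture [structure3d()] with a box
#' @param spacing lattice spacing, A
#' @param exclusion exclusion radius around existing atoms, A
#' @param seed integer seed for the jitter
#' @return the solvated [structure3d()]
#' @export
solvate_fixture <- function(s, spacing = 5.2, exclusion = 4.2, seed = 1L) {
  box <- s$box[1:3]
  set.seed(seed)
  g <- as.matrix(expand.grid(
    x = seq(spacing / 2, box[1] - spacing / 4, by = spacing),
    y = seq(spacing / 2, box[2] - spacing / 4, by = spacing),
    z = seq(spacing / 2, box[3] - spacing / 4, by = spacing)))
  g <- g + matrix(stats::runif(length(g), -0.5, 0.5), nrow(g), 3)
  g <- g %% matrix(box, nrow(g), 3, byrow = TRUE)
  keep <- rep(TRUE, nrow(g))
  for (r in seq_len(n_atoms(s))) {
    dv <- sweep(g, 2, s$xyz[r, ])
    dv <- dv - sweep(round(sweep(dv, 2, box, "/")), 2, box, "*")
    keep <- keep & rowSums(dv^2) >= exclusion^2
  }
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0) return(s)
  wat <- structure3d(
    data.frame(name = "W", element = "X", res_name = "W",
               res_id = seq_len(nrow(g)), chain = "W", mass = 72.06,
               charge = 0, is_bead = FALSE, stringsAsFactors = FALSE),
    g, box = s$box)
  combine_structures(s, wat, box = s$box)
}

#' Small NVE test system
#'
#' A 38-bead toy system (two toy lipids plus 32 coarse water sites) on a
#' loose lattice in a cubic box -- the standard fixture for energy
#' conservation and momentum checks.
#'
#' @param box_len cubic box edge, A
#' @return a [structure3d()]
#' @export
nve_fixture <- function(box_len = 30) {
  rows <- list(); xyz <- list(); k <- 0L
  pos <- as.matrix(expand.grid(x = seq(3, 27, by = 6.5),
                               y = seq(3, 27, by = 6.5),
                               z = seq(3, 27, by = 6.5)))[1:38, ]
  for (l in 1:2) {
    for (b in 1:3) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        name = c("HD", "TL1", "TL2")[b], element = "X", res_name = "TOY",
        res_id = l, chain = "L", mass = 72, charge = 0, is_bead = FALSE,
        stringsAsFactors = FALSE)
      xyz[[k]] <- pos[k, ] + c(0, 0, (b - 1) * 4.7)
    }
  }
  for (w in 1:32) {
    k <- k + 1L
    rows[[k]] <- data.frame(
      name = "W", element = "X", res_name = "W", res_id = w, chain = "W",
      mass = 72.06, charge = 0, is_bead = FALSE, stringsAsFactors = FALSE)
    xyz[[k]] <- pos[k, ]
  }
  structure3d(do.call(rbind, rows), do.call(rbind, xyz),
              box = c(box_len, box_len, box_len), title = "NVE toy fixture")
}
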