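# cg_mapper: atomistic -> coarse-grained bead mapping at ~4:1 resolution.
# Bead chemistry lives in editable YAML templates under
# inst/extdata/templates (protein.yaml, popc.yaml, toy3.yaml); the mapper
# itself only places beads at parent-atom centers of mass and wires up the
# bonded topology.

#' Construct a coarse-grained model
#'
#' @param beads a [structure3d()] with `is_bead = TRUE` atoms
#' @param classes character vector of bead polarity classes, one of
#'   `"P"` (polar), `"N"` (intermediate), `"C"` (apolar), `"Q"` (charged)
#' @param bonds data.frame `i, j, r0, k` (A, kJ mol^-1 A^-2); may be empty
#' @param angles data.frame `i, j, k_, theta0, k_angle` (degrees,
#'   kJ mol^-1 rad^-2); may be empty
#' @param elastic data.frame like `bonds`, filled by
#'   [build_elastic_network()]
#' @param backbone integer indices of backbone beads (one per protein
#'   residue)
#' @param phosphates integer indices of lipid phosphate/headgroup beads
#' @return an object of class `cg_model`
#' @export
cg_model <- function(beads, classes,
                     bonds = empty_bonds(), angles = empty_angles(),
                     elastic = empty_bonds(),
                     backbone = integer(0), phosphates = integer(0)) {
  stopifnot(inherits(beads, "mem_structure"))
  n <- n_atoms(beads)
  classes <- as.character(classes)
  if (length(classes) != n) stop("one class per bead required")
  if (!all(classes %in% c("P", "N", "C", "Q")))
    stop("bead classes must be P, N, C or Q")
  if (any(beads$atoms$charge != 0 & classes != "Q"))
    stop("nonzero charge is only allowed for class Q beads")
  .check_idx <- function(idx) {
    idx <- as.integer(idx)
    if (length(idx) && (min(idx) < 1 || max(idx) > n))
      stop("bead index out of range")
    idx
  }
  for (df in list(bonds, elastic)) {
    .check_idx(df$i); .check_idx(df$j)
  }
  .check_idx(angles$i); .check_idx(angles$j); .check_idx(angles$k_)
  structure(list(beads = beads, classes = classes,
                 bonds = bonds, angles = angles, elastic = elastic,
                 backbone = .check_idx(backbone),
                 phosphates = .check_idx(phosphates)),
            class = "cg_model")
}

#' @export
print.cg_model <- function(x, ...) {
  cat(sprintf(paste0("<cg_model> %d beads (%d backbone, %d phosphate), ",
                     "%d bonds, %d angles, %d elastic bonds\n"),
              n_atoms(x$beads), length(x$backbone), length(x$phosphates),
              nrow(x$bonds), nrow(x$angles), nrow(x$elastic)))
  invisible(x)
}

#' @rdname cg_model
#' @export
empty_bonds <- function() {
  data.frame(i = integer(0), j = integer(0), r0 = numeric(0), k = numeric(0))
}

#' @rdname cg_model
#' @export
empty_angles <- function() {
  data.frame(i = integer(0), j = integer(0), k_ = integer(0),
             theta0 = numeric(0), k_angle = numeric(0))
}

#' Packaged bead templates
#'
#' `protein_templates()` returns the per-residue bead table (one backbone
#' bead per residue at the N,CA,C,O center of mass; 0-2 side-chain beads
#' with polarity classes following side-chain hydrophobicity).
#' `lipid_template()` loads a lipid template by name: `"popc"` (13 beads:
#' zwitterionic headgroup pair, two glycerol linkers, 4+5 tail beads) or
#' `"toy3"` (3-bead head--tail--tail toy lipid used by the synthetic
#' fixtures).  Both are editable YAML files under
#' `system.file("extdata/templates", package = "memscale")`.
#'
#' @param path optional path to an alternative YAML template file
#' @return a named list (per residue type) of bead template lists
#' @export
protein_templates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata/templates/protein.yaml", package = "memscale")
  yaml::read_yaml(path)
}

#' @rdname protein_templates
#' @param name lipid template name (file stem under the template directory)
#' @export
lipid_template <- function(name = "popc", path = NULL) {
  if (is.null(path))
    path <- system.file("extdata/templates", paste0(name, ".yaml"),
                        package = "memscale")
  if (!file.exists(path)) stop("no lipid template '", name, "'")
  yaml::read_yaml(path)
}

# residues in file order, keyed by (chain, res_id) runs
.residue_runs <- function(atoms) {
  key <- paste(atoms$chain, atoms$res_id, sep = "|")
  idx <- which(key != c("", key[-length(key)]))
  starts <- idx
  ends <- c(idx[-1] - 1L, length(key))
  data.frame(start = starts, end = ends,
             res_id = atoms$res_id[starts],
             res_name = atoms$res_name[starts],
             chain = atoms$chain[starts],
             stringsAsFactors = FALSE)
}

.bead_from_parents <- function(s, idx, tpl) {
  m <- s$atoms$mass[idx]
  if (sum(m) <= 0) m <- rep(1, length(idx))
  list(xyz = colSums(s$xyz[idx, , drop = FALSE] * m) / sum(m),
       mass = if (!is.null(tpl$mass)) tpl$mass else sum(s$atoms$mass[idx]))
}

#' Map an atomistic protein to a coarse-grained model
#'
#' One backbone bead per residue at the center of mass of the backbone
#' atoms (N, CA, C, O -- whichever are present, so CA-trace fixtures map
#' too) and 0-2 side-chain beads at template parent-atom centers of mass.
#' Consecutive backbone beads within a chain are bonded (reference bond
#' length taken from the input geometry); side-chain beads are bonded to
#' their backbone bead.  Bead masses are parent-atom sums, so total mass
#' is conserved.
#'
#' @param s atomistic [structure3d()] with standard amino-acid residues
#' @param templates per-residue bead template table, see
#'   [protein_templates()]
#' @param bond_k backbone/side-chain bond force constant, kJ mol^-1 A^-2
#' @return a [cg_model()] with `backbone` filled (one bead per residue)
#' @export
map_protein <- function(s, templates = protein_templates(), bond_k = 25) {
  runs <- .residue_runs(s$atoms)
  missing <- setdiff(unique(runs$res_name), names(templates))
  if (length(missing))
    stop("mapping error: no template for residue type(s): ",
         paste(missing, collapse = ", "))
  bb_atoms <- c("N", "CA", "C", "O")
  rows <- list(); xyz <- list(); classes <- character(0)
  backbone <- integer(0)
  bonds_i <- integer(0); bonds_j <- integer(0)
  prev_bb <- NA_integer_; prev_chain <- ""
  nb <- 0L
  for (r in seq_len(nrow(runs))) {
    ridx <- runs$start[r]:runs$end[r]
    tlist <- templates[[runs$res_name[r]]]
    bb_idx <- NA_integer_
    for (tpl in tlist) {
      pa <- unlist(tpl$atoms)
      if (identical(tpl$name, "BB")) pa <- bb_atoms
      sel <- ridx[s$atoms$name[ridx] %in% pa]
      if (identical(tpl$name, "BB") && length(sel) == 0)
        stop("mapping error: residue ", runs$res_id[r], " (",
             runs$res_name[r], ") has no backbone atoms")
      if (length(sel) == 0) next  # side-chain parents absent (e.g. CA trace)
      b <- .bead_from_parents(s, sel, tpl)
      nb <- nb + 1L
      rows[[nb]] <- data.frame(
        name = tpl$name, element = "X", res_name = runs$res_name[r],
        res_id = runs$res_id[r], chain = runs$chain[r],
        mass = b$mass, charge = tpl$charge, is_bead = TRUE,
        stringsAsFactors = FALSE)
      xyz[[nb]] <- b$xyz
      classes <- c(classes, tpl$class)
      if (identical(tpl$name, "BB")) {
        bb_idx <- nb
        backbone <- c(backbone, nb)
      } else {
        # side-chain bead bonded to this residue's backbone bead,
        # SC2 chained onto SC1
        anchor <- if (identical(tpl$name, "SC2")) nb - 1L else bb_idx
        bonds_i <- c(bonds_i, anchor); bonds_j <- c(bonds_j, nb)
      }
    }
    if (!is.na(prev_bb) && identical(runs$chain[r], prev_chain)) {
      bonds_i <- c(bonds_i, prev_bb); bonds_j <- c(bonds_j, bb_idx)
    }
    prev_bb <- bb_idx; prev_chain <- runs$chain[r]
  }
  beads <- structure3d(do.call(rbind, rows), do.call(rbind, xyz),
                       box = s$box, title = s$title)
  r0 <- sqrt(rowSums((beads$xyz[bonds_i, , drop = FALSE] -
                      beads$xyz[bonds_j, , drop = FALSE])^2))
  bond_df <- if (length(bonds_i))
    data.frame(i = bonds_i, j = bonds_j, r0 = r0, k = bond_k)
  else empty_bonds()
  cg_model(beads, classes, bonds = bond_df, backbone = backbone)
}

#' Map atomistic lipids to coarse-grained beads
#'
#' Every residue in `s` matching the template's residue name becomes one
#' lipid: beads in template order at parent-atom centers of mass,
#' intra-lipid bonds and (tail-straightening) angles per template, and the
#' template's `phosphate` bead recorded in `phosphates`.
#'
#' @param s [structure3d()] containing the lipid residues
#' @param template a lipid template from [lipid_template()]
#' @return a [cg_model()] with `phosphates` filled (one per lipid)
#' @export
map_lipid <- function(s, template = lipid_template("popc")) {
  runs <- .residue_runs(s$atoms)
  if (!all(runs$res_name == template$residue))
    stop("mapping error: residue(s) ",
         paste(unique(runs$res_name[runs$res_name != template$residue]),
               collapse = ", "),
         " do not match lipid template '", template$residue, "'")
  nb_per <- length(template$beads)
  rows <- list(); xyz <- list(); classes <- character(0)
  phosphates <- integer(0)
  bonds <- list(); angles <- list()
  nb <- 0L
  for (r in seq_len(nrow(runs))) {
    ridx <- runs$start[r]:runs$end[r]
    base <- nb
    for (tpl in template$beads) {
      pa <- unlist(tpl$atoms)
      sel <- ridx[s$atoms$name[ridx] %in% pa]
      if (length(sel) == 0)
        stop("mapping error: lipid ", runs$res_id[r],
             ": no atoms match bead ", tpl$name,
             " (patterns: ", paste(pa, collapse = " "), ")")
      b <- .bead_from_parents(s, sel, tpl)
      nb <- nb + 1L
      rows[[nb]] <- data.frame(
        name = tpl$name, element = "X", res_name = template$residue,
        res_id = runs$res_id[r], chain = runs$chain[r],
        mass = b$mass, charge = tpl$charge, is_bead = TRUE,
        stringsAsFactors = FALSE)
      xyz[[nb]] <- b$xyz
      classes <- c(classes, tpl$class)
      if (isTRUE(tpl$phosphate)) phosphates <- c(phosphates, nb)
    }
    for (bd in template$bonds)
      bonds[[length(bonds) + 1L]] <- base + c(bd[1], bd[2])
    for (an in template$angles)
      angles[[length(angles) + 1L]] <- base + c(an[1], an[2], an[3])
  }
  beads <- structure3d(do.call(rbind, rows), do.call(rbind, xyz),
                       box = s$box, title = s$title)
  bm <- do.call(rbind, bonds)
  am <- do.call(rbind, angles)
  bond_df <- if (is.null(bm)) empty_bonds() else
    data.frame(i = bm[, 1], j = bm[, 2],
               r0 = template$bond_r0, k = template$bond_k)
  ang_df <- if (is.null(am)) empty_angles() else
    data.frame(i = am[, 1], j = am[, 2], k_ = am[, 3],
               theta0 = template$angle_theta0, k_angle = template$angle_k)
  cg_model(beads, classes, bonds = bond_df, angles = ang_df,
           phosphates = phosphates)
}

#' Map atomistic waters to coarse-grained water beads
#'
#' One neutral polar-class bead per four atomistic waters (floor), the
#' standard 4:1 water mapping.  Beads are laid out on a cubic lattice so
#' the result always has finite coordinates; builders that need solvated
#' boxes place them properly.
#'
#' @param n_aa_waters number of atomistic water molecules (>= 0)
#' @param spacing lattice spacing in Angstrom
#' @return a [cg_model()] with `floor(n_aa_waters / 4)` water beads
#' @export
map_water <- function(n_aa_waters, spacing = 4.7) {
  if (length(n_aa_waters) != 1 || is.na(n_aa_waters) || n_aa_waters < 0)
    stop("n_aa_waters must be a single count >= 0")
  n <- floor(n_aa_waters / 4)
  if (n == 0) {
    beads <- structure3d(
      data.frame(name = character(0), element = character(0),
                 res_name = character(0), res_id = integer(0),
                 chain = character(0), mass = numeric(0),
                 charge = numeric(0), is_bead = logical(0)),
      matrix(0, 0, 3))
    return(cg_model(beads, character(0)))
  }
  side <- ceiling(n^(1 / 3))
  g <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
  g <- as.matrix(g[seq_len(n), ]) * spacing
  beads <- structure3d(
    data.frame(name = "W", element = "X", res_name = "W",
               res_id = seq_len(n), chain = "W",
               mass = 72.06, charge = 0, is_bead = TRUE,
               stringsAsFactors = FALSE),
    g)
  cg_model(beads, rep("P", n))
}

#' Concatenate coarse-grained models
#'
#' Bead indices in bonds, angles, elastic bonds, backbone and phosphate
#' sets are offset so the combined model is self-consistent.
#'
#' @param ... `cg_model` objects
#' @param box box for the combined model
#' @return a [cg_model()]
#' @export
combine_cg <- function(..., box = NULL) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  parts <- parts[vapply(parts, function(p) n_atoms(p$beads) > 0, logical(1))]
  if (length(parts) == 0) stop("nothing to combine")
  off <- cumsum(c(0L, vapply(parts, function(p) n_atoms(p$beads), integer(1))))
  beads <- do.call(combine_structures, c(lapply(parts, `[[`, "beads"),
                                         list(box = box)))
  shift <- function(df, k, cols) { df[cols] <- df[cols] + k; df }
  bonds <- do.call(rbind, Map(function(p, k) shift(p$bonds, k, c("i", "j")),
                              parts, off[-length(off)]))
  elastic <- do.call(rbind, Map(function(p, k) shift(p$elastic, k, c("i", "j")),
                                parts, off[-length(off)]))
  angles <- do.call(rbind, Map(function(p, k) shift(p$angles, k, c("i", "j", "k_")),
                               parts, off[-length(off)]))
  cg_model(beads,
           unlist(lapply(parts, `[[`, "classes")),
           bonds = bonds, angles = angles, elastic = elastic,
           backbone = unlist(Map(function(p, k) p$backbone + k,
                                 parts, off[-length(off)])),
           phosphates = unlist(Map(function(p, k) p$phosphates + k,
                                   parts, off[-length(off)])))
}
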