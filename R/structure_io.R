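# structure_io: shared coordinate/topology data model plus PDB/GRO readers
# and writers.  Internal length unit is Angstrom everywhere; GRO files (nm)
# are converted on read and write.

#' Construct a molecular structure
#'
#' The common currency of all memscale modules: an ordered atom (or bead)
#' table plus an `n x 3` coordinate matrix in Angstrom and an optional
#' periodic box.
#'
#' @param atoms data.frame with columns `name`, `element`, `res_name`,
#'   `res_id` (integer, 1-based, preserved from the source file), `chain`,
#'   `mass` (amu, >= 0), `charge` (elementary charges) and `is_bead`
#'   (logical).  Missing columns are filled with defaults.
#' @param xyz numeric matrix, `n x 3`, Angstrom.  Must be finite.
#' @param box `NULL`, or numeric of length 3 (orthorhombic lengths, A) or 6
#'   (lengths + angles in degrees).
#' @param title optional title string.
#' @return An object of class `mem_structure`.
#' @export
#' @examples
#' s <- structure3d(data.frame(name = "CA", res_name = "ALA", res_id = 1),
#'                  matrix(0, 1, 3))
#' n_atoms(s)
structure3d <- function(atoms, xyz, box = NULL, title = "") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have 3 columns")
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  if (!all(is.finite(xyz))) stop("xyz must be finite")
  n <- nrow(xyz)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) != n) stop("atoms and xyz disagree on atom count")
  defaults <- list(name = "X", element = NA_character_, res_name = "UNK",
                   res_id = 1L, chain = "A", mass = 0, charge = 0,
                   is_bead = FALSE)
  for (col in names(defaults)) {
    if (is.null(atoms[[col]])) atoms[[col]] <- rep(defaults[[col]], n)
  }
  atoms$res_id <- as.integer(atoms$res_id)
  if (anyNA(atoms$element)) {
    miss <- is.na(atoms$element)
    atoms$element[miss] <- .guess_element(atoms$name[miss])
  }
  if (any(atoms$mass == 0 & !atoms$is_bead)) {
    z <- atoms$mass == 0 & !atoms$is_bead
    atoms$mass[z] <- .element_mass(atoms$element[z])
  }
  if (any(atoms$mass < 0)) stop("mass must be >= 0")
  box <- .check_box(box)
  structure(list(atoms = atoms[names(defaults)], xyz = xyz, box = box,
                 title = title),
            class = "mem_structure")
}

.check_box <- function(box) {
  if (is.null(box)) return(NULL)
  box <- as.numeric(box)
  if (length(box) == 3) box <- c(box, 90, 90, 90)
  if (length(box) != 6) stop("box must have length 3 or 6")
  if (any(box[1:3] <= 0)) stop("box lengths must be > 0")
  box
}

#' @export
print.mem_structure <- function(x, ...) {
  cat(sprintf("<mem_structure> %d atoms, %d residues%s\n",
              n_atoms(x), length(unique(x$atoms$res_id)),
              if (any(x$atoms$is_bead)) " (coarse-grained beads)" else ""))
  if (!is.null(x$box))
    cat(sprintf("  box: %.2f x %.2f x %.2f A\n", x$box[1], x$box[2], x$box[3]))
  if (nzchar(x$title)) cat("  title:", x$title, "\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `mem_structure`
#' @return integer atom count
#' @export
n_atoms <- function(s) nrow(s$xyz)

#' Mass-weighted center of mass
#'
#' @param s a `mem_structure`
#' @param idx optional atom indices; defaults to all atoms
#' @return length-3 numeric, Angstrom.  Falls back to the geometric center
#'   when the selected atoms carry zero total mass.
#' @export
center_of_mass <- function(s, idx = seq_len(n_atoms(s))) {
  m <- s$atoms$mass[idx]
  if (sum(m) <= 0) m <- rep(1, length(idx))
  colSums(s$xyz[idx, , drop = FALSE] * m) / sum(m)
}

#' Extract a subset of atoms as a new structure
#' @param s a `mem_structure`
#' @param idx atom indices to keep (order preserved)
#' @return a `mem_structure`
#' @export
subset_structure <- function(s, idx) {
  structure3d(s$atoms[idx, , drop = FALSE], s$xyz[idx, , drop = FALSE],
              box = s$box, title = s$title)
}

#' Concatenate structures
#' @param ... `mem_structure` objects
#' @param box box for the result (default: first non-NULL input box)
#' @return a `mem_structure`
#' @export
combine_structures <- function(..., box = NULL) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (is.null(box)) {
    for (p in parts) if (!is.null(p$box)) { box <- p$box; break }
  }
  atoms <- do.call(rbind, lapply(parts, function(p) p$atoms))
  xyz <- do.call(rbind, lapply(parts, function(p) p$xyz))
  structure3d(atoms, xyz, box = box, title = parts[[1]]$title)
}

# ---------------------------------------------------------------- readers

#' Read a molecular structure from PDB or GRO
#'
#' Coordinates are returned in Angstrom regardless of the source unit
#' (GRO nanometres are converted).  The periodic box is captured from a
#' CRYST1 record (PDB) or the final box line (GRO) when present.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`
#' @return a [structure3d()] object
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", gro = "gro",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") .parse_pdb(lines, path) else .parse_gro(lines, path)
}

.num_field <- function(txt, lineno, what) {
  x <- suppressWarnings(as.numeric(txt))
  bad <- is.na(x)
  if (any(bad)) {
    stop(sprintf("parse error at line %d: malformed %s field '%s'",
                 lineno[which(bad)[1]], what, txt[which(bad)[1]]))
  }
  x
}

.parse_pdb <- function(lines, path) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  # only first MODEL for a single-structure read
  if (length(model_starts) >= 2) {
    is_atom[seq_along(lines) >= model_starts[2]] <- FALSE
  }
  rec <- lines[is_atom]
  lineno <- which(is_atom)
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
  short <- nchar(rec) < 54
  if (any(short)) {
    stop(sprintf("parse error at line %d: ATOM record shorter than 54 columns",
                 lineno[which(short)[1]]))
  }
  name <- trimws(substr(rec, 13, 16))
  res_name <- trimws(substr(rec, 18, 20))
  chain <- substr(rec, 22, 22)
  chain[chain == " "] <- "A"
  res_id <- .num_field(substr(rec, 23, 26), lineno, "residue number")
  x <- .num_field(substr(rec, 31, 38), lineno, "x coordinate")
  y <- .num_field(substr(rec, 39, 46), lineno, "y coordinate")
  z <- .num_field(substr(rec, 47, 54), lineno, "z coordinate")
  element <- trimws(substr(rec, 77, 78))
  element[element == "" | is.na(element)] <- NA_character_
  box <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) >= 1) {
    b <- suppressWarnings(as.numeric(c(
      substr(cr[1], 7, 15), substr(cr[1], 16, 24), substr(cr[1], 25, 33),
      substr(cr[1], 34, 40), substr(cr[1], 41, 47), substr(cr[1], 48, 54))))
    if (!anyNA(b) && all(b[1:3] > 0)) box <- b
  }
  title <- sub("^TITLE\\s+", "", grep("^TITLE", lines, value = TRUE)[1])
  if (is.na(title)) title <- ""
  structure3d(
    data.frame(name = name, element = element, res_name = res_name,
               res_id = as.integer(round(res_id)), chain = chain,
               mass = 0, charge = 0, is_bead = FALSE,
               stringsAsFactors = FALSE),
    cbind(x, y, z), box = box, title = trimws(title))
}

.parse_gro <- function(lines, path) {
  if (length(lines) < 3) stop("parse error at line 1: truncated GRO file")
  title <- trimws(lines[1])
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms)) stop("parse error at line 2: bad atom count")
  if (length(lines) < 2 + natoms + 1)
    stop(sprintf("parse error at line %d: expected %d atom lines",
                 length(lines), natoms))
  rec <- lines[3:(2 + natoms)]
  lineno <- 3:(2 + natoms)
  res_id <- .num_field(substr(rec, 1, 5), lineno, "residue number")
  res_name <- trimws(substr(rec, 6, 10))
  name <- trimws(substr(rec, 11, 15))
  x <- .num_field(substr(rec, 21, 28), lineno, "x coordinate")
  y <- .num_field(substr(rec, 29, 36), lineno, "y coordinate")
  z <- .num_field(substr(rec, 37, 44), lineno, "z coordinate")
  boxline <- trimws(lines[3 + natoms])
  bv <- suppressWarnings(as.numeric(strsplit(boxline, "\\s+")[[1]]))
  box <- NULL
  if (length(bv) >= 3 && !anyNA(bv[1:3]) && all(bv[1:3] > 0))
    box <- c(bv[1:3] * 10, 90, 90, 90)  # nm -> A, orthorhombic
  structure3d(
    data.frame(name = name, element = NA_character_, res_name = res_name,
               res_id = as.integer(round(res_id)), chain = "A",
               mass = 0, charge = 0, is_bead = FALSE,
               stringsAsFactors = FALSE),
    cbind(x, y, z) * 10, box = box, title = title)
}

# ---------------------------------------------------------------- writers

#' Write a structure to PDB or GRO
#'
#' @param s a `mem_structure`
#' @param path output file path
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`
#' @return `path`, invisibly
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", gro = "gro",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  lines <- if (format == "pdb") .format_pdb(s) else .format_gro(s)
  writeLines(lines, path)
  invisible(path)
}

.pdb_atom_name <- function(name) {
  # 1-3 character names start in column 14 by PDB convention
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         sprintf(" %-3s", name))
}

.format_pdb <- function(s) {
  a <- s$atoms
  n <- n_atoms(s)
  out <- character(0)
  if (nzchar(s$title)) out <- c(out, sprintf("TITLE     %s", s$title))
  if (!is.null(s$box)) {
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                          s$box[1], s$box[2], s$box[3],
                          s$box[4], s$box[5], s$box[6]))
  }
  rec <- ifelse(a$is_bead, "HETATM", "ATOM  ")
  rec[a$res_name %in% c("HOH", "WAT", "TIP3", "SOL", "ION", "NA", "CL")] <- "HETATM"
  el <- substr(a$element, 1, 2)
  out <- c(out, sprintf("%s%5d %s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                        rec,
                        (seq_len(n) - 1L) %% 99999L + 1L,
                        .pdb_atom_name(a$name),
                        substr(a$res_name, 1, 3),
                        substr(a$chain, 1, 1),
                        a$res_id %% 10000L,
                        s$xyz[, 1], s$xyz[, 2], s$xyz[, 3],
                        1, 0, formatC(el, width = 2)))
  c(out, "END")
}

.format_gro <- function(s) {
  a <- s$atoms
  n <- n_atoms(s)
  box <- if (is.null(s$box)) c(0, 0, 0) else s$box[1:3] / 10
  c(if (nzchar(s$title)) s$title else "memscale structure",
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            a$res_id %% 100000L,
            substr(a$res_name, 1, 5),
            substr(a$name, 1, 5),
            (seq_len(n) - 1L) %% 99999L + 1L,
            s$xyz[, 1] / 10, s$xyz[, 2] / 10, s$xyz[, 3] / 10),
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
}
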