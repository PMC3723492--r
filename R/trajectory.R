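# Trajectory container + on-disk formats: multi-MODEL PDB (read) and a
# documented plain-text frame format (native read/write):
#
#   MEMTRAJ 1
#   natoms <n>
#   frame <time_fs> <lx> <ly> <lz>        # box lengths in Angstrom
#   <x> <y> <z>                           # one line per atom, Angstrom
#   ... repeated per frame

#' Construct a trajectory
#'
#' @param topology a [structure3d()] giving atom identities; every frame
#'   must have the same atom count.
#' @param coords list of `n x 3` coordinate matrices (Angstrom)
#' @param times numeric vector of frame times in fs (non-decreasing)
#' @param boxes optional list of per-frame boxes (length-3 or length-6);
#'   defaults to the topology box
#' @return an object of class `mem_trajectory`
#' @export
trajectory <- function(topology, coords, times = NULL, boxes = NULL) {
  if (!inherits(topology, "mem_structure")) stop("topology must be a mem_structure")
  if (!is.list(coords) || length(coords) == 0) stop("coords must be a non-empty list")
  n <- n_atoms(topology)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != n || ncol(m) != 3)
      stop("every frame must be a ", n, " x 3 matrix")
    storage.mode(m) <- "double"
    m
  })
  nf <- length(coords)
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf) stop("times must match frame count")
  if (is.unsorted(times)) stop("frame times must be non-decreasing")
  if (is.null(boxes)) boxes <- rep(list(topology$box), nf)
  if (length(boxes) != nf) stop("boxes must match frame count")
  boxes <- lapply(boxes, .check_box)
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times), boxes = boxes),
            class = "mem_trajectory")
}

#' @export
print.mem_trajectory <- function(x, ...) {
  cat(sprintf("<mem_trajectory> %d frames x %d atoms, t = %g..%g fs\n",
              n_frames(x), n_atoms(x$topology),
              x$times[1], x$times[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `mem_trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) length(traj$coords)

#' Extract one frame of a trajectory as a structure
#' @param traj a `mem_trajectory`
#' @param i frame index
#' @return a `mem_structure` with that frame's coordinates and box
#' @export
frame_structure <- function(traj, i) {
  structure3d(traj$topology$atoms, traj$coords[[i]],
              box = traj$boxes[[i]], title = traj$topology$title)
}

#' Read a trajectory from multi-MODEL PDB or the native frame format
#'
#' @param path file path
#' @param topology required for the native format (which stores only
#'   coordinates); ignored for PDB
#' @param format `"auto"`, `"pdb"` or `"memtraj"`
#' @return a [trajectory()] object
#' @export
read_trajectory <- function(path, topology = NULL,
                            format = c("auto", "pdb", "memtraj")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1, warn = FALSE)
    format <- if (grepl("^MEMTRAJ", first)) "memtraj" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    top <- .parse_pdb(lines, path)
    starts <- grep("^MODEL", lines)
    if (length(starts) <= 1) {
      return(trajectory(top, list(top$xyz), times = 0))
    }
    ends <- c(starts[-1], length(lines) + 1)
    coords <- vector("list", length(starts))
    for (k in seq_along(starts)) {
      blk <- lines[starts[k]:(ends[k] - 1)]
      s <- .parse_pdb(c(blk, "END"), path)
      coords[[k]] <- s$xyz
    }
    return(trajectory(top, coords, times = seq_along(coords) - 1))
  }
  if (is.null(topology)) stop("native trajectory format needs a topology")
  if (!grepl("^MEMTRAJ", lines[1])) stop("parse error at line 1: not a MEMTRAJ file")
  natoms <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]][2])
  if (is.na(natoms) || natoms != n_atoms(topology))
    stop("trajectory atom count disagrees with topology")
  pos <- 3L
  coords <- list(); times <- numeric(0); boxes <- list()
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    hdr <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    if (hdr[1] != "frame")
      stop(sprintf("parse error at line %d: expected frame header", pos))
    v <- suppressWarnings(as.numeric(hdr[-1]))
    if (length(v) < 4 || anyNA(v))
      stop(sprintf("parse error at line %d: bad frame header", pos))
    block <- lines[(pos + 1):(pos + natoms)]
    m <- matrix(suppressWarnings(as.numeric(
      unlist(strsplit(trimws(block), "\\s+")))), ncol = 3, byrow = TRUE)
    if (anyNA(m) || nrow(m) != natoms)
      stop(sprintf("parse error near line %d: bad coordinate block", pos + 1))
    coords[[length(coords) + 1L]] <- m
    times <- c(times, v[1])
    boxes[[length(boxes) + 1L]] <- v[2:4]
    pos <- pos + natoms + 1L
  }
  trajectory(topology, coords, times = times, boxes = boxes)
}

#' Write a trajectory
#'
#' Multi-MODEL PDB or the native plain-text frame format (see
#' [read_trajectory()] for its layout).
#'
#' @param traj a `mem_trajectory`
#' @param path output path
#' @param format `"auto"` (by extension: `.pdb` or anything else ->
#'   native), `"pdb"` or `"memtraj"`
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path, format = c("auto", "pdb", "memtraj")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "pdb") "pdb" else "memtraj"
  if (format == "pdb") {
    out <- character(0)
    for (k in seq_len(n_frames(traj))) {
      s <- frame_structure(traj, k)
      body <- .format_pdb(s)
      body <- body[body != "END"]
      out <- c(out, sprintf("MODEL     %4d", k), body, "ENDMDL")
    }
    writeLines(c(out, "END"), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("MEMTRAJ 1", sprintf("natoms %d", n_atoms(traj$topology))), con)
    for (k in seq_len(n_frames(traj))) {
      b <- traj$boxes[[k]]
      if (is.null(b)) b <- c(0, 0, 0)
      writeLines(sprintf("frame %.6g %.6f %.6f %.6f",
                         traj$times[k], b[1], b[2], b[3]), con)
      m <- traj$coords[[k]]
      writeLines(sprintf("%.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
    }
  }
  invisible(path)
}
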