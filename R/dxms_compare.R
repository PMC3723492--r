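# dxms_compare: score consistency between a structural model/trajectory
# and deuterium-exchange decrement data.  Fragments with a large exchange
# decrement on membrane binding should correspond to residues the model
# buries below the headgroup plane; fragments with no decrement should
# stay exposed.  Weak decrements are interpreted as partial/transient
# burial and scored with half weight.

#' Read / write DXMS fragment tables
#'
#' Tab-separated columns: `res_start`, `res_end` (inclusive residue ids),
#' `decrement_pct` (percent decrease in deuteration upon membrane
#' binding, 0-100) and `incubation_s` (seconds).
#'
#' @param path file path
#' @return data.frame of fragments
#' @export
read_dxms <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("res_start", "res_end", "decrement_pct", "incubation_s")
  if (!all(need %in% names(df)))
    stop("DXMS table must have columns: ", paste(need, collapse = ", "))
  if (any(df$res_start > df$res_end)) stop("res_start must be <= res_end")
  if (any(df$decrement_pct < 0 | df$decrement_pct > 100))
    stop("decrement_pct must lie in [0, 100]")
  df
}

#' @rdname read_dxms
#' @param fragments fragment data.frame
#' @export
write_dxms <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Classify DXMS fragments by decrement size
#'
#' `strong` for a decrement of at least 70%, `weak` for a positive
#' decrement under 40%, `none` for zero, and `intermediate` for values in
#' [40, 70) (flagged, between the published thresholds).
#'
#' @param fragments data.frame with a `decrement_pct` column
#' @param strong_min,weak_max class thresholds, percent
#' @return the data.frame with a `class` column added
#' @export
classify_fragments <- function(fragments, strong_min = 70, weak_max = 40) {
  d <- fragments$decrement_pct
  cl <- rep("intermediate", length(d))
  cl[d >= strong_min] <- "strong"
  cl[d > 0 & d < weak_max] <- "weak"
  cl[d == 0] <- "none"
  fragments$class <- cl
  fragments
}

#' Per-residue burial profile of a trajectory
#'
#' Depth mode: a residue counts as buried in a frame when its side-chain
#' center of mass lies below the proximal leaflet's mean phosphate plane
#' (toward the bilayer center).  SASA mode: buried when the residue's
#' solvent-accessible surface area (rolling probe, sphere-point
#' quadrature) is below `sasa_threshold`.  The profile is the buried
#' fraction of frames per residue.
#'
#' @param traj a [trajectory()]
#' @param mf a [membrane_frame()] or list of one per frame (depth mode)
#' @param res_ids residues to profile (default: all protein residues)
#' @param mode `"depth"` or `"sasa"`
#' @param sasa_threshold A^2 (sasa mode)
#' @param probe_radius solvent probe radius, A (sasa mode)
#' @return data.frame of class `burial_profile`: `res_id`, `fraction`
#'   in [0, 1]; attribute `rule` describes the burial criterion
#' @export
burial_profile <- function(traj, mf = NULL, res_ids = NULL,
                           mode = c("depth", "sasa"),
                           sasa_threshold = 20, probe_radius = 1.4) {
  mode <- match.arg(mode)
  atoms <- traj$topology$atoms
  if (is.null(res_ids))
    res_ids <- unique(atoms$res_id[!(atoms$res_name %in%
                                       c("POPC", "TOY", "W", "HOH"))])
  nf <- n_frames(traj)
  if (mode == "depth") {
    if (is.null(mf)) stop("depth mode needs membrane frame(s)")
    mfl <- if (inherits(mf, "membrane_frame")) rep(list(mf), nf) else mf
    bb <- c("N", "CA", "C", "O")
    frac <- vapply(res_ids, function(rid) {
      ridx <- which(atoms$res_id == rid &
                      !(atoms$res_name %in% c("POPC", "TOY", "W", "HOH")))
      sc <- ridx[!(atoms$name[ridx] %in% bb)]
      if (length(sc) == 0) sc <- ridx
      m <- atoms$mass[sc]; if (sum(m) <= 0) m <- rep(1, length(sc))
      buried <- vapply(seq_len(nf), function(k) {
        z <- sum(traj$coords[[k]][sc, 3] * m) / sum(m)
        f <- mfl[[k]]
        # proximal leaflet: the phosphate plane nearer the residue
        if (abs(z - f$phosphate_z_upper) <= abs(z - f$phosphate_z_lower))
          z < f$phosphate_z_upper else z > f$phosphate_z_lower
      }, logical(1))
      mean(buried)
    }, numeric(1))
    rule <- "side-chain c.o.m. below proximal phosphate plane"
  } else {
    if (any(traj$topology$atoms$is_bead))
      stop("sasa mode needs an atomistic model; use mode = 'depth'")
    frac <- vapply(res_ids, function(rid) {
      buried <- vapply(seq_len(nf), function(k) {
        s <- frame_structure(traj, k)
        residue_sasa(s, rid, probe_radius) < sasa_threshold
      }, logical(1))
      mean(buried)
    }, numeric(1))
    rule <- sprintf("residue SASA < %g A^2 (probe %g A)",
                    sasa_threshold, probe_radius)
  }
  out <- data.frame(res_id = res_ids, fraction = frac)
  attr(out, "rule") <- rule
  class(out) <- c("burial_profile", "data.frame")
  out
}

# van der Waals radii for the SASA quadrature
.VDW <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8, X = 1.7)

#' Solvent-accessible surface area of one residue
#'
#' Shrake-Rupley style sphere-point quadrature: points on each atom's
#' solvent-expanded sphere count as accessible when outside every other
#' atom's expanded sphere.
#'
#' @param s a [structure3d()]
#' @param res_id residue to measure
#' @param probe_radius probe radius, A
#' @param n_points quadrature points per atom
#' @return area in A^2
#' @export
residue_sasa <- function(s, res_id, probe_radius = 1.4, n_points = 96) {
  ridx <- which(s$atoms$res_id == res_id)
  if (length(ridx) == 0) stop("residue ", res_id, " not found")
  rad <- .VDW[s$atoms$element]
  rad[is.na(rad)] <- 1.7
  rad <- rad + probe_radius
  # golden-spiral points on the unit sphere
  i <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i / n_points)
  theta <- pi * (1 + sqrt(5)) * i
  sph <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  total <- 0
  for (a in ridx) {
    pts <- sweep(sph * rad[a], 2, s$xyz[a, ], "+")
    acc <- rep(TRUE, n_points)
    for (b in seq_len(n_atoms(s))) {
      if (b == a) next
      if (sum((s$xyz[b, ] - s$xyz[a, ])^2) > (rad[a] + rad[b])^2) next
      dv <- sweep(pts, 2, s$xyz[b, ])
      acc <- acc & rowSums(dv^2) > rad[b]^2
      if (!any(acc)) break
    }
    total <- total + 4 * pi * rad[a]^2 * mean(acc)
  }
  total
}

#' Consistency score between burial profile and DXMS fragments
#'
#' A fragment is predicted protected when the mean burial fraction over
#' its residues is at least `burial_threshold`.  Full-weight matches:
#' strong fragments predicted protected, and no-decrement fragments
#' predicted exposed.  Weak and intermediate fragments score half weight
#' when partially buried (mean fraction strictly between 0 and the
#' threshold).  The overall score is weighted matches / total weight over
#' scorable fragments; fragments outside the model are listed unscored.
#'
#' @param bp a [burial_profile()]
#' @param fragments a classified fragment table (see
#'   [classify_fragments()]; classified automatically if no `class`
#'   column present)
#' @param burial_threshold mean burial fraction defining "protected"
#' @return list with `table` (per-fragment: class, mean burial,
#'   predicted, match weight, scored flag) and `score` (overall fraction
#'   matched, in [0, 1]; `NA` when nothing is scorable)
#' @export
consistency_score <- function(bp, fragments, burial_threshold = 0.5) {
  if (is.null(fragments$class)) fragments <- classify_fragments(fragments)
  rows <- lapply(seq_len(nrow(fragments)), function(r) {
    rng <- fragments$res_start[r]:fragments$res_end[r]
    hit <- bp$res_id %in% rng
    if (!any(hit)) {
      return(data.frame(res_start = fragments$res_start[r],
                        res_end = fragments$res_end[r],
                        class = fragments$class[r], mean_burial = NA_real_,
                        predicted = NA_character_, match = NA_real_,
                        scored = FALSE, stringsAsFactors = FALSE))
    }
    mb <- mean(bp$fraction[hit])
    predicted <- if (mb >= burial_threshold) "protected" else "exposed"
    match <- switch(fragments$class[r],
      strong = as.numeric(predicted == "protected"),
      none = as.numeric(predicted == "exposed"),
      # weak/intermediate: half-weight match for partial burial
      if (mb > 0 && mb < burial_threshold) 0.5 else 0)
    data.frame(res_start = fragments$res_start[r],
               res_end = fragments$res_end[r],
               class = fragments$class[r], mean_burial = mb,
               predicted = predicted, match = match, scored = TRUE,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  scored <- tab[tab$scored, , drop = FALSE]
  weight <- ifelse(scored$class %in% c("strong", "none"), 1, 0.5)
  score <- if (nrow(scored)) sum(scored$match) / sum(weight) else NA_real_
  list(table = tab, score = score)
}
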